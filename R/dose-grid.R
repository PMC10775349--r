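#' Grouped dose structure for the simulated cohort
#'
#' Defines the dose groups over which individuals are simulated and over
#' which case counts are collapsed before Poisson fitting: the dose-interval
#' bounds, the central dose estimate per group, the person-year offset used
#' in the Poisson model, and the number of simulated individuals per group.
#'
#' @param group_edges numeric matrix (or 2-column coercible) with one row
#'   per group giving the lower and upper dose bound in Gy; the upper bound
#'   of the last group may be `Inf`.
#' @param central_doses numeric vector of central dose estimates per group
#'   (Gy), all strictly positive.
#' @param person_years numeric vector of person-year offsets per group, all
#'   strictly positive.
#' @param n_individuals integer vector of simulated individuals per group,
#'   all at least 1.
#'
#' @return An object of class `"dose_grid"`: a list with the validated
#'   fields plus `n_groups` and `group_of_individual` (the group index of
#'   each simulated individual, individuals ordered by group).
#' @seealso [default_dose_grid()]
#' @export
dose_grid <- function(group_edges, central_doses, person_years, n_individuals) {
  group_edges <- as.matrix(group_edges)
  if (ncol(group_edges) != 2L)
    stop("'group_edges' must have two columns (lower, upper bound in Gy)")
  G <- nrow(group_edges)
  central_doses <- as.numeric(central_doses)
  person_years <- as.numeric(person_years)
  n_individuals <- as.integer(n_individuals)
  if (length(central_doses) != G || length(person_years) != G ||
      length(n_individuals) != G)
    stop("'central_doses', 'person_years' and 'n_individuals' must each have one entry per group")
  if (any(!is.finite(central_doses)) || any(central_doses <= 0))
    stop("'central_doses' must be finite and > 0")
  if (any(!is.finite(person_years)) || any(person_years <= 0))
    stop("'person_years' must be finite and > 0")
  if (any(is.na(n_individuals)) || any(n_individuals < 1L))
    stop("'n_individuals' must all be >= 1")
  structure(
    list(group_edges = group_edges,
         central_doses = central_doses,
         person_years = person_years,
         n_individuals = n_individuals,
         n_groups = G,
         group_of_individual = rep.int(seq_len(G), n_individuals)),
    class = "dose_grid")
}

#' Default five-group dose grid
#'
#' The default grid uses the five bone-marrow dose groups 0-0.07, 0.08-0.19,
#' 0.20-0.99, 1.00-2.49 and >= 2.50 Gy, with central dose estimates close to
#' the person-year-weighted group means of a Life Span Study-like cohort and
#' the central estimate of the uppermost group fixed at 2 Gy.  Person-years
#' are apportioned with the bulk of follow-up at low dose, as in cohorts of
#' this kind; simulated individuals are allocated proportionally to
#' person-years and the Poisson offsets are taken equal to the resulting
#' cohort counts, so case generation and model fitting share one exposure
#' structure.
#'
#' @param n_total total number of simulated individuals to spread over the
#'   groups (default 1000).
#' @return A [dose_grid()] object with 5 groups.
#' @export
default_dose_grid <- function(n_total = 1000L) {
  n_total <- as.integer(n_total)
  if (is.na(n_total) || n_total < 5L)
    stop("'n_total' must be at least one individual per group")
  edges <- rbind(c(0, 0.07), c(0.08, 0.19), c(0.20, 0.99),
                 c(1.00, 2.49), c(2.50, Inf))
  central <- c(0.02, 0.12, 0.45, 1.5, 2.0)
  py_prop <- c(2100, 330, 390, 120, 50)
  py_prop <- py_prop / sum(py_prop)
  n_ind <- largest_remainder_round(py_prop * n_total)
  n_ind[n_ind < 1L] <- 1L
  dose_grid(edges, central, person_years = as.numeric(n_ind),
            n_individuals = n_ind)
}

## integer apportionment preserving the total
largest_remainder_round <- function(x) {
  fl <- floor(x)
  rem <- x - fl
  short <- round(sum(x)) - sum(fl)
  if (short > 0) {
    top <- order(rem, decreasing = TRUE)[seq_len(short)]
    fl[top] <- fl[top] + 1
  }
  as.integer(fl)
}

#' @export
print.dose_grid <- function(x, ...) {
  cat("Dose grid with", x$n_groups, "groups,",
      sum(x$n_individuals), "individuals\n")
  df <- data.frame(
    lower_Gy = x$group_edges[, 1], upper_Gy = x$group_edges[, 2],
    central_Gy = x$central_doses, person_years = x$person_years,
    n = x$n_individuals)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Lognormal error-magnitude specification
#'
#' The four log-scale standard deviations of the composite
#' Berkson-classical multiplicative error model: shared and unshared
#' Berkson components (acting on the true dose) and shared and unshared
#' classical components (acting on the surrogate dose).  A log-scale SD of
#' 0.2 corresponds to a geometric standard deviation of exp(0.2), commonly
#' labelled a "20%" error.
#'
#' @param sigma_shared_berkson,sigma_unshared_berkson log-scale SDs of the
#'   shared and unshared Berkson components (>= 0).
#' @param sigma_shared_classical,sigma_unshared_classical log-scale SDs of
#'   the shared and unshared classical components (>= 0).
#' @return An object of class `"error_spec"`.
#' @export
error_spec <- function(sigma_shared_berkson = 0,
                       sigma_unshared_berkson = 0,
                       sigma_shared_classical = 0,
                       sigma_unshared_classical = 0) {
  vals <- c(sigma_shared_berkson, sigma_unshared_berkson,
            sigma_shared_classical, sigma_unshared_classical)
  if (length(vals) != 4L || any(!is.finite(vals)) || any(vals < 0))
    stop("all four error SDs must be finite and >= 0")
  structure(
    list(sigma_shared_berkson = sigma_shared_berkson,
         sigma_unshared_berkson = sigma_unshared_berkson,
         sigma_shared_classical = sigma_shared_classical,
         sigma_unshared_classical = sigma_unshared_classical),
    class = "error_spec")
}

#' @export
print.error_spec <- function(x, ...) {
  cat(sprintf(
    "Error spec (log-scale SD): Berkson shared %.3g / unshared %.3g; classical shared %.3g / unshared %.3g\n",
    x$sigma_shared_berkson, x$sigma_unshared_berkson,
    x$sigma_shared_classical, x$sigma_unshared_classical))
  invisible(x)
}

#' Excess relative risk model
#'
#' The linear-quadratic excess relative risk model
#' `RR(d) = 1 + alpha * d + beta * d^2`, with a log-scale intercept `kappa`
#' multiplying the baseline rate.  The intercept here is the model's free
#' baseline parameter and is distinct from any noise draw; the relative
#' risk must be positive over the support of the dose grid.
#'
#' @param alpha linear ERR coefficient (/Gy).
#' @param beta quadratic ERR coefficient (/Gy^2); 0 gives the linear model.
#' @param kappa log baseline scale (dimensionless), default 0.
#' @return An object of class `"risk_model"`.
#' @export
risk_model <- function(alpha, beta = 0, kappa = 0) {
  if (!is.finite(alpha) || !is.finite(beta) || !is.finite(kappa))
    stop("risk model coefficients must be finite")
  structure(list(alpha = alpha, beta = beta, kappa = kappa),
            class = "risk_model")
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("ERR model: RR(d) = 1 + %g d + %g d^2 (kappa = %g)\n",
              x$alpha, x$beta, x$kappa))
  invisible(x)
}

## relative risk 1 + a d + b d^2, no validity check
relative_risk <- function(dose, alpha, beta) 1 + alpha * dose + beta * dose^2

check_rr_positive <- function(grid, model) {
  dmax <- max(grid$central_doses)
  dd <- seq(0, dmax, length.out = 256L)
  rr <- relative_risk(dd, model$alpha, model$beta)
  if (any(rr <= 0))
    stop(sprintf("relative risk non-positive at dose %.4g Gy on the grid support",
                 dd[which(rr <= 0)[1L]]))
  invisible(TRUE)
}
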