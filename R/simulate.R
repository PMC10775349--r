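#' Simulate a nested ensemble of true and surrogate doses
#'
#' Draws one meta-simulation's dose ensemble under the composite
#' Berkson-classical lognormal error model.  For individual `i` in dose
#' group `k(i)` and sub-simulation `j`,
#' \deqn{D_{true,i,j} = D_{cent,k(i)} e^{-(s_B^2+u_B^2)/2}
#'       e^{s_B \epsilon_j + u_B \delta_{i,j}}}{
#'       D_true = D_cent exp(-(sB^2+uB^2)/2) exp(sB*eps_j + uB*delta_ij)}
#' \deqn{D_{surr,i,j} = D_{cent,k(i)} e^{-(s_C^2+u_C^2)/2}
#'       e^{s_C \mu_j + u_C \kappa_{i,j}}}{
#'       D_surr = D_cent exp(-(sC^2+uC^2)/2) exp(sC*mu_j + uC*kap_ij)}
#' where `s_B, u_B` are the shared/unshared Berkson log-scale SDs, `s_C,
#' u_C` the classical ones, and all noise draws are iid standard normal.
#' The shared draws `eps_j` and `mu_j` are common to every individual
#' within sub-simulation `j`; the unshared draws are independent across
#' individuals and sub-simulations.  The leading factors make each dose's
#' theoretical mean equal its group central dose.
#'
#' @param grid a [dose_grid()].
#' @param errors an [error_spec()].
#' @param m number of sub-simulations (>= 1).
#' @param rng_seed optional integer seed; when supplied the ensemble is
#'   reproducible bit-for-bit.
#' @return An object of class `"dose_ensemble"`: list with `true_doses` and
#'   `surrogate_doses` (matrices, individuals x sub-simulations),
#'   `group_of_individual`, the `grid`, the `errors`, and `seed_record`.
#' @export
simulate_dose_ensemble <- function(grid, errors, m, rng_seed = NULL) {
  stopifnot(inherits(grid, "dose_grid"), inherits(errors, "error_spec"))
  m <- as.integer(m)
  if (is.na(m) || m < 1L) stop("'m' must be an integer >= 1")
  if (!is.null(rng_seed)) set.seed(rng_seed)

  n <- sum(grid$n_individuals)
  grp <- grid$group_of_individual
  cent <- grid$central_doses[grp]

  sB <- errors$sigma_shared_berkson
  uB <- errors$sigma_unshared_berkson
  sC <- errors$sigma_shared_classical
  uC <- errors$sigma_unshared_classical

  ## shared draws: one per sub-simulation, common to all individuals
  eps <- rnorm(m)
  mu <- rnorm(m)
  ## unshared draws: independent per individual per sub-simulation
  delta <- matrix(rnorm(n * m), n, m)
  kap <- matrix(rnorm(n * m), n, m)

  true_log <- sweep(uB * delta, 2L, sB * eps, `+`)
  surr_log <- sweep(uC * kap, 2L, sC * mu, `+`)
  true_doses <- cent * exp(-0.5 * (sB^2 + uB^2)) * exp(true_log)
  surrogate_doses <- cent * exp(-0.5 * (sC^2 + uC^2)) * exp(surr_log)

  structure(
    list(true_doses = true_doses,
         surrogate_doses = surrogate_doses,
         group_of_individual = grp,
         grid = grid, errors = errors, m = m,
         seed_record = rng_seed),
    class = "dose_ensemble")
}

#' @export
print.dose_ensemble <- function(x, ...) {
  cat(sprintf("Dose ensemble: %d individuals x %d sub-simulations\n",
              nrow(x$true_doses), x$m))
  print(x$errors)
  invisible(x)
}

#' Average Pearson correlation between individuals' true-dose series
#'
#' Computes the sample Pearson correlation between the true-dose series
#' (across sub-simulations) of pairs of distinct individuals, averaged over
#' pairs.  With no unshared Berkson error every individual shares the same
#' multiplicative factor, so the correlation is exactly 1; with no shared
#' component it is approximately 0.  For shared and unshared log-scale SDs
#' `s` and `u` the population value is
#' `(exp(s^2) - 1) / (exp(s^2 + u^2) - 1)`.
#'
#' @param ensemble a [simulate_dose_ensemble()] result with `m >= 3`.
#' @param n_pairs number of random distinct pairs to average over
#'   (default 100); ignored when `pairs` is supplied.
#' @param pairs optional 2-column matrix of individual indices selecting
#'   the pairs explicitly.
#' @param rng_seed optional seed for the random pair sampling.
#' @return Average pairwise correlation (scalar).
#' @export
true_dose_correlation <- function(ensemble, n_pairs = 100L, pairs = NULL,
                                  rng_seed = NULL) {
  stopifnot(inherits(ensemble, "dose_ensemble"))
  n <- nrow(ensemble$true_doses)
  if (n < 2L) stop("need at least 2 individuals to correlate")
  if (ensemble$m < 3L) stop("need at least 3 sub-simulations")
  if (is.null(pairs)) {
    if (!is.null(rng_seed)) set.seed(rng_seed)
    pairs <- t(replicate(n_pairs, sample.int(n, 2L)))
  }
  pairs <- as.matrix(pairs)
  cors <- vapply(seq_len(nrow(pairs)), function(r) {
    a <- ensemble$true_doses[pairs[r, 1L], ]
    b <- ensemble$true_doses[pairs[r, 2L], ]
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b)
  }, numeric(1))
  mean(cors, na.rm = TRUE)
}

#' Generate cancer case counts for a meta-simulation
#'
#' Assigns each individual a case probability proportional to their
#' relative risk `1 + alpha*D + beta*D^2` evaluated at the true dose and
#' averaged over the ensemble's sub-simulations, then draws a single
#' multinomial sample of `n_cases` cases over individuals.  The same case
#' vector is shared by every sub-simulation within the meta-simulation.
#'
#' @param ensemble a [simulate_dose_ensemble()] result.
#' @param model a [risk_model()] giving the true coefficients.
#' @param n_cases total number of cases to distribute (default 250).
#' @param rng_seed optional integer seed.
#' @return Integer vector of case counts, one per individual, summing to
#'   `n_cases`.
#' @export
simulate_cases <- function(ensemble, model, n_cases = 250L, rng_seed = NULL) {
  stopifnot(inherits(ensemble, "dose_ensemble"), inherits(model, "risk_model"))
  n_cases <- as.integer(n_cases)
  if (is.na(n_cases) || n_cases < 1L) stop("'n_cases' must be >= 1")
  rr_bar <- case_probabilities(ensemble, model, normalise = FALSE)
  if (any(rr_bar <= 0)) {
    bad <- which(rr_bar <= 0)[1L]
    stop(sprintf(
      "non-positive relative risk for individual %d (mean true dose %.4g Gy)",
      bad, mean(ensemble$true_doses[bad, ])))
  }
  if (!is.null(rng_seed)) set.seed(rng_seed)
  drop(rmultinom(1L, n_cases, rr_bar / sum(rr_bar)))
}

## per-individual mean relative risk over sub-simulations (optionally
## normalised to probabilities); the analytic target of the multinomial
case_probabilities <- function(ensemble, model, normalise = TRUE) {
  d1 <- rowMeans(ensemble$true_doses)
  d2 <- rowMeans(ensemble$true_doses^2)
  rr <- 1 + model$alpha * d1 + model$beta * d2
  if (normalise) rr / sum(rr) else rr
}

#' Collapse an ensemble and case vector to grouped data
#'
#' Sums cases into dose groups and attaches the per-group dose summary a
#' given estimator needs: the group mean of true doses over individuals and
#' sub-simulations (`"mean-true"`, the regression-calibration dose), the
#' group mean of surrogate doses from one designated sub-simulation
#' (`"single-surrogate-draw"`, the unadjusted dose), or the full set of `m`
#' per-sub-simulation group-mean true-dose vectors
#' (`"per-subsim-vectors"`, the MCML/BMA/FMA input).
#'
#' @param ensemble a [simulate_dose_ensemble()] result.
#' @param cases integer case counts per individual (from
#'   [simulate_cases()]).
#' @param dose_choice one of `"mean-true"`, `"single-surrogate-draw"`,
#'   `"per-subsim-vectors"`.
#' @param surrogate_draw index of the designated sub-simulation used by
#'   `"single-surrogate-draw"` (default 1).
#' @return An object of class `"grouped_data"`: list with `cases`,
#'   `offsets`, `calibrated_dose` and (for `"per-subsim-vectors"`)
#'   `dose_vectors`, an `m x n_groups` matrix.
#' @export
collapse_to_groups <- function(ensemble, cases,
                               dose_choice = c("mean-true",
                                               "single-surrogate-draw",
                                               "per-subsim-vectors"),
                               surrogate_draw = 1L) {
  stopifnot(inherits(ensemble, "dose_ensemble"))
  dose_choice <- match.arg(dose_choice)
  grp <- ensemble$group_of_individual
  if (length(cases) != length(grp))
    stop("'cases' must have one entry per individual in the ensemble")
  grid <- ensemble$grid
  G <- grid$n_groups
  gcases <- as.integer(rowsum(as.numeric(cases), grp)[, 1L])
  n_g <- as.numeric(grid$n_individuals)

  out <- list(cases = gcases, offsets = grid$person_years,
              calibrated_dose = NULL, dose_vectors = NULL,
              dose_choice = dose_choice)
  if (dose_choice == "mean-true") {
    out$calibrated_dose <- rowsum(rowMeans(ensemble$true_doses), grp)[, 1L] / n_g
  } else if (dose_choice == "single-surrogate-draw") {
    j <- as.integer(surrogate_draw)
    if (j < 1L || j > ensemble$m) stop("'surrogate_draw' out of range")
    out$calibrated_dose <-
      rowsum(ensemble$surrogate_doses[, j], grp)[, 1L] / n_g
  } else {
    ## m x G matrix: group means of true doses per sub-simulation
    gm <- rowsum(ensemble$true_doses, grp) / n_g
    out$dose_vectors <- unname(t(gm))
    out$calibrated_dose <- colMeans(out$dose_vectors)
  }
  names(out$calibrated_dose) <- NULL
  structure(out, class = "grouped_data")
}

#' @export
print.grouped_data <- function(x, ...) {
  cat(sprintf("Grouped data (%s): %d groups, %d cases\n",
              x$dose_choice, length(x$cases), sum(x$cases)))
  print(data.frame(cases = x$cases, offset = x$offsets,
                   dose_Gy = x$calibrated_dose), row.names = FALSE)
  if (!is.null(x$dose_vectors))
    cat(sprintf("with %d per-sub-simulation dose vectors\n",
                nrow(x$dose_vectors)))
  invisible(x)
}

#' Simulate one complete meta-simulation
#'
#' Convenience wrapper generating everything a full estimator comparison
#' needs for one meta-simulation: the dose ensemble, the shared case
#' vector, and the three grouped views (regression-calibration doses,
#' single-surrogate-draw doses for the unadjusted fit, and the full
#' per-sub-simulation dose-vector set for MCML/BMA/FMA).
#'
#' @inheritParams simulate_dose_ensemble
#' @inheritParams simulate_cases
#' @param keep_ensemble keep the full individual-level ensemble in the
#'   result (default `FALSE` to bound memory in large runs).
#' @return An object of class `"meta_sim"` with elements `rc_data`,
#'   `unadj_data`, `vector_data` (all [collapse_to_groups()] results),
#'   `cases_by_group`, `grid`, `errors`, `seed_record` and optionally
#'   `ensemble`.
#' @export
simulate_meta <- function(grid, errors, model, m = 1000L, n_cases = 250L,
                          rng_seed = NULL, keep_ensemble = FALSE) {
  if (!is.null(rng_seed)) set.seed(rng_seed)
  ensemble <- simulate_dose_ensemble(grid, errors, m)
  cases <- simulate_cases(ensemble, model, n_cases)
  out <- list(
    rc_data = collapse_to_groups(ensemble, cases, "mean-true"),
    unadj_data = collapse_to_groups(ensemble, cases, "single-surrogate-draw"),
    vector_data = collapse_to_groups(ensemble, cases, "per-subsim-vectors"),
    grid = grid, errors = errors, m = m, n_cases = n_cases,
    seed_record = rng_seed)
  out$cases_by_group <- out$rc_data$cases
  if (keep_ensemble) out$ensemble <- ensemble
  structure(out, class = "meta_sim")
}

#' @export
print.meta_sim <- function(x, ...) {
  cat(sprintf("Meta-simulation: %d sub-simulations, %d cases\n",
              x$m, sum(x$cases_by_group)))
  print(x$errors)
  invisible(x)
}

#' Export a dose ensemble to CSV (long format)
#'
#' Writes one row per individual per sub-simulation with columns
#' `sub_id, individual_id, group, true_dose, surrogate_dose` (plus an
#' optional `meta_id` column).
#'
#' @param ensemble a [simulate_dose_ensemble()] result.
#' @param path file path to write.
#' @param meta_id optional meta-simulation identifier column value.
#' @return The path, invisibly.
#' @export
export_ensemble <- function(ensemble, path, meta_id = NA_integer_) {
  stopifnot(inherits(ensemble, "dose_ensemble"))
  n <- nrow(ensemble$true_doses)
  m <- ensemble$m
  df <- data.frame(
    meta_id = meta_id,
    sub_id = rep(seq_len(m), each = n),
    individual_id = rep(seq_len(n), times = m),
    group = rep(ensemble$group_of_individual, times = m),
    true_dose = as.vector(ensemble$true_doses),
    surrogate_dose = as.vector(ensemble$surrogate_doses))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
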