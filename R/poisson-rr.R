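## Poisson linear relative-risk likelihood, ML fitting and profile CIs.
##
## The model: cases y_g ~ Poisson(mu_g), mu_g = exp(kappa) * PY_g * RR(d_g),
## RR(d) = 1 + alpha*d + beta*d^2, subject to RR(d_g) > 0 at every observed
## group dose.  Log-likelihood terms constant in the parameters (log y!)
## are dropped consistently throughout, so likelihood *differences* and AIC
## comparisons are exact.

## raw log-likelihood at explicit (kappa, alpha, beta); -Inf outside the
## positivity region (compiled kernel)
ll_poisson_rr <- function(y, off, dose, alpha, beta, kappa)
  cpp_ll_poisson_rr(y, off, dose, alpha, beta, kappa)

## profile log-likelihood over kappa: exp(kappa_hat) = sum(y)/sum(off*RR)
## has closed form because exp(kappa) is a pure scale on the means
ll_profile_kappa <- function(y, off, dose, alpha, beta)
  cpp_ll_profile_kappa(y, off, dose, alpha, beta)

kappa_hat_given <- function(y, off, dose, alpha, beta) {
  rr <- relative_risk(dose, alpha, beta)
  log(sum(y) / sum(off * rr))
}

#' Poisson linear relative-risk log-likelihood
#'
#' Evaluates the grouped Poisson log-likelihood
#' `sum_g [ y_g log(mu_g) - mu_g ]` (additive constants dropped) with
#' `mu_g = exp(kappa) * PY_g * (1 + alpha d_g + beta d_g^2)`.  Under
#' `form = "linear"` the quadratic coefficient is fixed at zero.
#'
#' @param data a [collapse_to_groups()] result (uses `cases` and
#'   `offsets`).
#' @param dose per-group dose vector (Gy); defaults to the data's
#'   calibrated dose.
#' @param model a [risk_model()] supplying `alpha`, `beta`, `kappa`.
#' @param form `"linear"` or `"linear-quadratic"`.
#' @return Scalar log-likelihood.
#' @export
loglik_linear_rr <- function(data, dose = data$calibrated_dose, model,
                             form = c("linear-quadratic", "linear")) {
  stopifnot(inherits(data, "grouped_data"), inherits(model, "risk_model"))
  form <- match.arg(form)
  beta <- if (form == "linear") 0 else model$beta
  rr <- relative_risk(dose, model$alpha, beta)
  if (any(rr <= 0))
    stop(sprintf("relative risk non-positive at group dose %.4g Gy",
                 dose[which(rr <= 0)[1L]]))
  ll_poisson_rr(data$cases, data$offsets, dose, model$alpha, beta,
                model$kappa)
}

## coarse-scan + local-optimise maximisation of a 1-d profile likelihood
## over an interval (lo, hi); returns list(par, value)
maximise_1d <- function(fn, lo, hi, n_scan = 60L) {
  xs <- seq(lo, hi, length.out = n_scan)
  vals <- vapply(xs, fn, numeric(1))
  i <- which.max(vals)
  bl <- xs[max(1L, i - 1L)]
  bu <- xs[min(n_scan, i + 1L)]
  op <- optimize(fn, lower = bl, upper = bu, maximum = TRUE,
                 tol = 1e-10)
  if (op$objective < vals[i]) list(par = xs[i], value = vals[i])
  else list(par = op$maximum, value = op$objective)
}

## feasible alpha interval for a linear fit: 1 + alpha*d > 0 for all d > 0
alpha_bounds <- function(dose) {
  eps <- 1e-9
  c(-1 / max(dose) + eps, 1e4)
}

## feasible beta interval given alpha
beta_bounds <- function(dose, alpha) {
  eps <- 1e-9
  lo <- max(-(1 + alpha * dose) / dose^2) + eps
  c(lo, 1e4)
}

#' Fit the Poisson linear relative-risk model by maximum likelihood
#'
#' Maximises the grouped Poisson log-likelihood over `(kappa, alpha)`
#' (linear form) or `(kappa, alpha, beta)` (linear-quadratic form), with
#' the intercept profiled out analytically and the search restricted to
#' the region where every group's relative risk is positive.  Returns the
#' point estimates, profile-likelihood confidence intervals, the maximised
#' log-likelihood and the AIC.
#'
#' @inheritParams loglik_linear_rr
#' @param ci compute profile-likelihood intervals (default `TRUE`).
#' @param level confidence level for the intervals (default 0.95).
#' @param method_tag provenance label stored in the result.
#' @return An object of class `"fit_result"` with fields `alpha`, `beta`
#'   (`NA` for the linear form), `kappa`, `ci_alpha`, `ci_beta`, `loglik`,
#'   `aic`, `converged`, `ci_flags` and `method_tag`.
#' @export
fit_linear_rr <- function(data, dose = data$calibrated_dose,
                          form = c("linear-quadratic", "linear"),
                          ci = TRUE, level = 0.95,
                          method_tag = "poisson_rr") {
  stopifnot(inherits(data, "grouped_data"))
  form <- match.arg(form)
  y <- data$cases
  off <- data$offsets
  if (sum(y) < 1) stop("need at least one case to fit")
  if (any(dose <= 0)) stop("group doses must be positive")
  if (diff(range(dose)) < 1e-12)
    stop("all group doses equal: the dose-response slope is unidentifiable")

  converged <- TRUE
  if (form == "linear") {
    ab <- alpha_bounds(dose)
    op <- maximise_1d(function(a) ll_profile_kappa(y, off, dose, a, 0),
                      ab[1L], ab[2L])
    alpha <- op$par
    beta <- NA_real_
    llmax <- op$value
    npar <- 2L
  } else {
    ab <- alpha_bounds(dose)
    lin <- maximise_1d(function(a) ll_profile_kappa(y, off, dose, a, 0),
                       ab[1L], ab[2L])
    negpen <- function(p) {
      v <- ll_profile_kappa(y, off, dose, p[1L], p[2L])
      if (!is.finite(v)) {
        rr <- relative_risk(dose, p[1L], p[2L])
        return(1e10 + 1e6 * sum(pmax(0, -rr)))
      }
      -v
    }
    op <- optim(c(lin$par, 0), negpen, method = "Nelder-Mead",
                control = list(reltol = 1e-14, maxit = 4000L))
    ## restart once from the solution to escape simplex collapse
    op2 <- optim(op$par, negpen, method = "Nelder-Mead",
                 control = list(reltol = 1e-14, maxit = 4000L))
    if (op2$value < op$value) op <- op2
    converged <- op$convergence == 0L
    alpha <- op$par[1L]
    beta <- op$par[2L]
    llmax <- -op$value
    npar <- 3L
  }
  kappa <- kappa_hat_given(y, off, dose, alpha, if (is.na(beta)) 0 else beta)
  fr <- structure(
    list(alpha = alpha, beta = beta, kappa = kappa,
         ci_alpha = c(NA_real_, NA_real_), ci_beta = c(NA_real_, NA_real_),
         loglik = llmax, aic = -2 * llmax + 2 * npar, npar = npar,
         form = form, converged = converged,
         ci_flags = character(0), method_tag = method_tag),
    class = "fit_result")
  if (ci) {
    prof <- profile_functions(y, off, dose, form, alpha, beta)
    ca <- profile_interval(prof$alpha, alpha, llmax, level,
                           prof$alpha_limits)
    fr$ci_alpha <- ca$interval
    fr$ci_flags <- c(fr$ci_flags, ca$flags)
    if (form == "linear-quadratic") {
      cb <- profile_interval(prof$beta, beta, llmax, level,
                             prof$beta_limits)
      fr$ci_beta <- cb$interval
      fr$ci_flags <- c(fr$ci_flags, cb$flags)
    }
  }
  fr
}

## builds the per-coefficient profile log-likelihood functions; for the
## linear-quadratic form profiling one coefficient requires an inner 1-d
## maximisation over the other (kappa always analytic)
profile_functions <- function(y, off, dose, form, alpha_hat, beta_hat) {
  if (form == "linear") {
    list(alpha = function(a) ll_profile_kappa(y, off, dose, a, 0),
         alpha_limits = alpha_bounds(dose))
  } else {
    prof_a <- function(a) {
      bb <- beta_bounds(dose, a)
      if (bb[1L] >= bb[2L]) return(-Inf)
      cpp_profile_over_beta(y, off, dose, a, bb[1L], bb[2L])
    }
    prof_b <- function(b) {
      ## feasible alpha given beta: 1 + a d + b d^2 > 0
      lo <- max(-(1 + b * dose^2) / dose) + 1e-9
      if (lo >= 1e4) return(-Inf)
      cpp_profile_over_alpha(y, off, dose, b, lo, 1e4)
    }
    list(alpha = prof_a, alpha_limits = c(-1e4, 1e4),
         beta = prof_b, beta_limits = c(-1e4, 1e4))
  }
}

## one-sided profile-likelihood bound by geometric bracket expansion then
## bisection to tolerance 1e-6 on the log-likelihood scale
profile_bound <- function(prof, mle, llmax, drop, side, limit) {
  target <- llmax - drop
  step <- max(0.25, abs(mle) * 0.5)
  x_in <- mle
  x_out <- NA_real_
  for (i in 1:60) {
    cand <- mle + side * step
    if ((side < 0 && cand <= limit) || (side > 0 && cand >= limit)) {
      ## hit the constraint/search boundary
      v <- prof(limit + side * -1e-9)
      if (is.finite(v) && v > target)
        return(list(bound = limit, flag = "boundary"))
      x_out <- limit + side * -1e-9
      break
    }
    v <- prof(cand)
    if (!is.finite(v) || v < target) { x_out <- cand; break }
    x_in <- cand
    step <- step * 2
  }
  if (is.na(x_out))
    return(list(bound = side * Inf, flag = "unbounded"))
  ## bisection between x_in (above target) and x_out (below target)
  for (i in 1:200) {
    mid <- (x_in + x_out) / 2
    v <- prof(mid)
    if (is.finite(v) && v >= target) x_in <- mid else x_out <- mid
    if (abs(x_out - x_in) < 1e-10) break
    if (is.finite(v) && abs(v - target) < 1e-6) { x_in <- mid; break }
  }
  list(bound = x_in, flag = character(0))
}

profile_interval <- function(prof, mle, llmax, level, limits) {
  drop <- qchisq(level, df = 1) / 2
  lo <- profile_bound(prof, mle, llmax, drop, side = -1, limit = limits[1L])
  hi <- profile_bound(prof, mle, llmax, drop, side = +1, limit = limits[2L])
  list(interval = c(lo$bound, hi$bound), flags = c(lo$flag, hi$flag))
}

#' Profile-likelihood confidence interval for one coefficient
#'
#' Returns the set of coefficient values whose profile log-likelihood lies
#' within `qchisq(level, 1)/2` (1.92 at 95%) of the maximum, located by
#' geometric bracket expansion from the MLE followed by bisection.  Bounds
#' truncated by the relative-risk positivity constraint are flagged
#' `"boundary"`; sides on which the profile never drops by the threshold
#' are flagged `"unbounded"`.
#'
#' @inheritParams fit_linear_rr
#' @param coefficient `"alpha"` or `"beta"`.
#' @return List with `interval` (length 2), `mle`, and `flags`.
#' @export
profile_ci <- function(data, dose = data$calibrated_dose,
                       form = c("linear-quadratic", "linear"),
                       coefficient = c("alpha", "beta"), level = 0.95) {
  form <- match.arg(form)
  coefficient <- match.arg(coefficient)
  if (form == "linear" && coefficient == "beta")
    stop("the linear form has no quadratic coefficient")
  fit <- fit_linear_rr(data, dose, form, ci = TRUE, level = level)
  if (coefficient == "alpha")
    list(interval = fit$ci_alpha, mle = fit$alpha, flags = fit$ci_flags)
  else
    list(interval = fit$ci_beta, mle = fit$beta, flags = fit$ci_flags)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("Poisson linear-RR fit [%s, %s]\n", x$method_tag, x$form))
  cat(sprintf("  alpha = %.4g  (95%% CI %.4g, %.4g)\n",
              x$alpha, x$ci_alpha[1L], x$ci_alpha[2L]))
  if (!is.na(x$beta))
    cat(sprintf("  beta  = %.4g  (95%% CI %.4g, %.4g)\n",
                x$beta, x$ci_beta[1L], x$ci_beta[2L]))
  cat(sprintf("  kappa = %.4g; loglik = %.4f; AIC = %.4f; converged: %s\n",
              x$kappa, x$loglik, x$aic, x$converged))
  if (length(x$ci_flags))
    cat("  CI flags:", paste(x$ci_flags, collapse = ", "), "\n")
  invisible(x)
}

#' Serialise a fit result to a flat record
#'
#' @param x a `"fit_result"` or `"posterior_summary"`.
#' @param ... extra columns (scenario, meta id, ...) prepended to the
#'   record.
#' @return One-row `data.frame`.
#' @export
as_record <- function(x, ...) UseMethod("as_record")

#' @export
as_record.fit_result <- function(x, ...) {
  data.frame(...,
             method = x$method_tag,
             alpha = x$alpha, alpha_lo = x$ci_alpha[1L],
             alpha_hi = x$ci_alpha[2L],
             beta = x$beta, beta_lo = x$ci_beta[1L],
             beta_hi = x$ci_beta[2L],
             kappa = x$kappa, loglik = x$loglik, aic = x$aic,
             converged = x$converged, bgr_max = NA_real_,
             stringsAsFactors = FALSE)
}
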