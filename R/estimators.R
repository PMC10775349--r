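## The five dose-error-correction estimators.  Each consumes one
## meta-simulation (a "meta_sim" from simulate_meta()) and returns a
## fit_result (or, for the Bayesian estimator, a posterior_summary).
## All except the unadjusted fit use true-dose summaries, so classical
## error affects only the unadjusted regression.

#' Unadjusted regression on surrogate doses
#'
#' Plain Poisson linear relative-risk fit at the group-mean surrogate
#' doses from one designated sub-simulation (one shared and one unshared
#' classical draw).  This is the only estimator exposed to classical
#' error; averaging surrogates over sub-simulations would cancel it.
#'
#' @param meta_data a [simulate_meta()] result.
#' @param form `"linear"` or `"linear-quadratic"`.
#' @return A `"fit_result"`.
#' @export
fit_unadjusted <- function(meta_data, form = c("linear-quadratic", "linear")) {
  stopifnot(inherits(meta_data, "meta_sim"))
  form <- match.arg(form)
  fit_linear_rr(meta_data$unadj_data, form = form,
                method_tag = "unadjusted")
}

#' Regression calibration
#'
#' Poisson linear relative-risk fit at the per-group mean of the true
#' doses, averaged over individuals and sub-simulations -- the conditional
#' expectation of true dose given group membership, i.e. the classical
#' regression-calibration substitution.
#'
#' @inheritParams fit_unadjusted
#' @return A `"fit_result"`.
#' @export
fit_regression_calibration <- function(meta_data,
                                       form = c("linear-quadratic",
                                                "linear")) {
  stopifnot(inherits(meta_data, "meta_sim"))
  form <- match.arg(form)
  fit_linear_rr(meta_data$rc_data, form = form,
                method_tag = "regression_calibration")
}

#' Monte Carlo maximum likelihood
#'
#' Maximises the Monte Carlo likelihood
#' `L(theta) = (1/m) * sum_j L(theta; cases, dose vector j)`
#' over `(kappa, alpha[, beta])`, where the `m` dose vectors are the
#' per-sub-simulation group means of the true doses.  Confidence
#' intervals are profile-likelihood intervals on this averaged
#' likelihood.  With `m = 1` this reduces to an ordinary single-vector
#' fit; with all vectors identical it coincides with regression
#' calibration.
#'
#' @inheritParams fit_unadjusted
#' @param level confidence level (default 0.95).
#' @return A `"fit_result"`.
#' @export
fit_mcml <- function(meta_data, form = c("linear-quadratic", "linear"),
                     level = 0.95) {
  form <- match.arg(form)
  gd <- vector_grouped_data(meta_data)
  y <- gd$cases; off <- gd$offsets
  dv <- gd$dose_vectors
  quad <- form == "linear-quadratic"

  start_fit <- fit_linear_rr(gd, dose = colMeans(dv), form = form, ci = FALSE)
  start <- c(start_fit$kappa, start_fit$alpha,
             if (quad) start_fit$beta)

  negll <- function(p) {
    v <- cpp_ll_mcml(y, off, dv, p[2L], if (quad) p[3L] else 0, p[1L])
    if (!is.finite(v)) 1e10 else -v
  }
  op <- optim(start, negll, method = "Nelder-Mead",
              control = list(reltol = 1e-13, maxit = 5000L))
  op2 <- optim(op$par, negll, method = "Nelder-Mead",
               control = list(reltol = 1e-13, maxit = 5000L))
  if (op2$value < op$value) op <- op2
  kappa <- op$par[1L]; alpha <- op$par[2L]
  beta <- if (quad) op$par[3L] else NA_real_
  llmax <- -op$value
  npar <- if (quad) 3L else 2L

  ## numeric profile over the nuisance parameters for each coefficient
  prof_alpha <- function(a) {
    if (quad) {
      o <- optim(c(kappa, if (is.na(beta)) 0 else beta), function(q) {
        v <- cpp_ll_mcml(y, off, dv, a, q[2L], q[1L])
        if (!is.finite(v)) 1e10 else -v
      }, method = "Nelder-Mead", control = list(reltol = 1e-11))
      -o$value
    } else {
      -optimize(function(k) {
        v <- cpp_ll_mcml(y, off, dv, a, 0, k)
        if (!is.finite(v)) 1e10 else -v
      }, lower = kappa - 15, upper = kappa + 15, tol = 1e-9)$objective
    }
  }
  fr <- structure(
    list(alpha = alpha, beta = beta, kappa = kappa,
         ci_alpha = c(NA_real_, NA_real_), ci_beta = c(NA_real_, NA_real_),
         loglik = llmax, aic = -2 * llmax + 2 * npar, npar = npar,
         form = form, converged = op$convergence == 0L,
         ci_flags = character(0), method_tag = "mcml"),
    class = "fit_result")
  ca <- profile_interval(prof_alpha, alpha, llmax, level, c(-1e4, 1e4))
  fr$ci_alpha <- ca$interval
  fr$ci_flags <- c(fr$ci_flags, ca$flags)
  if (quad) {
    prof_beta <- function(b) {
      o <- optim(c(kappa, alpha), function(q) {
        v <- cpp_ll_mcml(y, off, dv, q[2L], b, q[1L])
        if (!is.finite(v)) 1e10 else -v
      }, method = "Nelder-Mead", control = list(reltol = 1e-11))
      -o$value
    }
    cb <- profile_interval(prof_beta, beta, llmax, level, c(-1e4, 1e4))
    fr$ci_beta <- cb$interval
    fr$ci_flags <- c(fr$ci_flags, cb$flags)
  }
  fr
}

#' Frequentist model averaging over dose vectors
#'
#' Fits the Poisson linear relative-risk model by maximum likelihood to
#' every per-sub-simulation dose vector, recovers a per-fit standard
#' deviation from the profile-likelihood interval as
#' `min(mle - lower, upper - mle) / 1.96`, draws `k_samples` normal
#' samples per coefficient per fit, and pools them with AIC weights
#' `exp(-AIC_j/2) / sum_k exp(-AIC_k/2)` (the exponent carries the
#' negative sign, so better-fitting vectors get more weight).  The
#' central estimate is the weighted mean of the pooled samples and the
#' 95% interval their weighted 2.5 and 97.5 centiles.
#'
#' Setting `symmetric_sd = FALSE` enables an asymmetric variant that uses
#' separate SDs below and above the MLE, recovered from the two CI arms;
#' it is prone to occasional very wide arms and is off by default.
#'
#' @inheritParams fit_unadjusted
#' @param k_samples normal draws per coefficient per dose-vector fit
#'   (default 100).
#' @param rng_seed optional seed for the normal draws.
#' @param symmetric_sd use the single symmetric recovered SD (default
#'   `TRUE`).
#' @return An object of class `"fma_result"`: per-vector fits (`fits`
#'   data frame), `aic_weights`, pooled weighted `samples` per
#'   coefficient, `central` and `ci` per coefficient, and the count of
#'   dropped (non-converged) vectors.
#' @export
fma <- function(meta_data, form = c("linear-quadratic", "linear"),
                k_samples = 100L, rng_seed = NULL, symmetric_sd = TRUE) {
  form <- match.arg(form)
  gd <- vector_grouped_data(meta_data)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  dv <- gd$dose_vectors
  m <- nrow(dv)
  quad <- form == "linear-quadratic"

  one <- function(j) {
    f <- tryCatch(fit_linear_rr(gd, dose = dv[j, ], form = form),
                  error = function(e) NULL)
    if (is.null(f) || !f$converged) return(NULL)
    sda <- recovered_sd(f$alpha, f$ci_alpha, symmetric_sd)
    sdb <- if (quad) recovered_sd(f$beta, f$ci_beta, symmetric_sd) else NULL
    if (!all(is.finite(unlist(c(sda, sdb))))) return(NULL)
    list(alpha = f$alpha, beta = f$beta, aic = f$aic,
         sd_alpha = sda, sd_beta = sdb)
  }
  fits <- lapply(seq_len(m), one)
  keep <- !vapply(fits, is.null, logical(1))
  n_dropped <- sum(!keep)
  fits <- fits[keep]
  if (!length(fits)) stop("no dose-vector fit converged; cannot model-average")

  aics <- vapply(fits, `[[`, numeric(1), "aic")
  w <- exp(-(aics - min(aics)) / 2)   # max-AIC subtraction guards overflow
  w <- w / sum(w)

  draw <- function(mle, sdrec) {
    if (symmetric_sd) rnorm(k_samples, mle, sdrec$sd)
    else {
      z <- rnorm(k_samples)
      mle + ifelse(z < 0, sdrec$sd_lower, sdrec$sd_upper) * z
    }
  }
  alpha_draws <- lapply(fits, function(f) draw(f$alpha, f$sd_alpha))
  samples <- list(alpha = data.frame(
    value = unlist(alpha_draws),
    weight = rep(w / k_samples, each = k_samples)))
  if (quad) {
    beta_draws <- lapply(fits, function(f) draw(f$beta, f$sd_beta))
    samples$beta <- data.frame(
      value = unlist(beta_draws),
      weight = rep(w / k_samples, each = k_samples))
  }
  central <- vapply(samples, function(s)
    sum(s$value * s$weight) / sum(s$weight), numeric(1))
  ci <- lapply(samples, function(s)
    weighted_quantile(s$value, s$weight, c(0.025, 0.975)))

  structure(
    list(fits = data.frame(
           alpha = vapply(fits, `[[`, numeric(1), "alpha"),
           beta = if (quad) vapply(fits, `[[`, numeric(1), "beta")
                  else NA_real_,
           aic = aics),
         aic_weights = w, samples = samples,
         central = central, ci = ci,
         n_dropped = n_dropped, k_samples = k_samples,
         symmetric_sd = symmetric_sd, form = form,
         method_tag = "fma"),
    class = "fma_result")
}

## accept either a full meta-simulation or a grouped dataset that already
## carries the per-sub-simulation dose vectors
vector_grouped_data <- function(x) {
  gd <- if (inherits(x, "grouped_data")) x
        else if (inherits(x, "meta_sim")) x$vector_data
        else stop("need a 'meta_sim' or 'grouped_data' object")
  if (is.null(gd$dose_vectors))
    stop("per-sub-simulation dose vectors missing")
  gd
}

## SD recovery from a profile-likelihood interval
recovered_sd <- function(mle, ci, symmetric) {
  lo <- mle - ci[1L]
  hi <- ci[2L] - mle
  if (symmetric) list(sd = min(lo, hi) / 1.96)
  else list(sd_lower = lo / 1.96, sd_upper = hi / 1.96)
}

## weighted quantiles of a sample (lower step interpolation on the
## cumulative weight)
weighted_quantile <- function(x, w, probs) {
  o <- order(x)
  x <- x[o]
  cw <- cumsum(w[o]) / sum(w)
  vapply(probs, function(p) x[which(cw >= p)[1L]], numeric(1))
}

#' @export
print.fma_result <- function(x, ...) {
  cat(sprintf("FMA over %d dose-vector fits (%d dropped), %s form\n",
              nrow(x$fits), x$n_dropped, x$form))
  cat(sprintf("  alpha = %.4g (95%% CI %.4g, %.4g)\n",
              x$central[["alpha"]], x$ci$alpha[1L], x$ci$alpha[2L]))
  if (!is.null(x$ci$beta))
    cat(sprintf("  beta  = %.4g (95%% CI %.4g, %.4g)\n",
                x$central[["beta"]], x$ci$beta[1L], x$ci$beta[2L]))
  invisible(x)
}

#' @export
as_record.fma_result <- function(x, ...) {
  quad <- !is.null(x$ci$beta)
  data.frame(...,
             method = "fma",
             alpha = x$central[["alpha"]],
             alpha_lo = x$ci$alpha[1L], alpha_hi = x$ci$alpha[2L],
             beta = if (quad) x$central[["beta"]] else NA_real_,
             beta_lo = if (quad) x$ci$beta[1L] else NA_real_,
             beta_hi = if (quad) x$ci$beta[2L] else NA_real_,
             kappa = NA_real_, loglik = NA_real_, aic = NA_real_,
             converged = TRUE, bgr_max = NA_real_,
             stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## estimator registry: built-in methods plus a plug-in slot for external
## estimators (e.g. extended regression calibration variants)

.estimator_registry <- new.env(parent = emptyenv())

builtin_estimators <- function()
  c("unadjusted", "regression_calibration", "mcml", "bma", "fma")

#' Register an external estimator
#'
#' Adds a plug-in estimator to the registry so scenario runs can request
#' it by name alongside the built-in methods.  The function is called as
#' `fn(meta_data, form, settings, rng_seed)` and must return either a
#' `"fit_result"`, an object with an [as_record()] method, or a one-row
#' data frame in the common record layout.
#'
#' @param name method name (must not clash with a built-in).
#' @param fn estimator function.
#' @return `name`, invisibly.
#' @export
register_estimator <- function(name, fn) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  if (name %in% builtin_estimators())
    stop("'", name, "' is a built-in estimator")
  assign(name, fn, envir = .estimator_registry)
  invisible(name)
}

#' Names of available estimators
#' @return Character vector of built-in plus registered method names.
#' @export
estimator_names <- function()
  c(builtin_estimators(), ls(.estimator_registry))
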