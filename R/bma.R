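## Quasi-2DMC with Bayesian model averaging: the posterior over
## (kappa, alpha[, beta]) is a mixture over the m candidate dose vectors,
##   p(theta | Y) = sum_k p_k * p(theta | Y, dose vector k),
## with mixture weights p_k parameterised by softmax variables
## lambda_1..lambda_{m-1} (the m-th category is the reference).  Both theta
## and lambda are sampled by Metropolis-Hastings (compiled sampler).

#' Softmax mixture weights
#'
#' Maps the unbounded weight parameters `lambda_1..lambda_{m-1}` to the
#' mixture probabilities
#' `p_j = exp(lambda_j) / (1 + sum_k exp(lambda_k))` for `j < m` and
#' `p_m = 1 / (1 + sum_k exp(lambda_k))`, computed stably.
#'
#' @param lambdas numeric vector of length `m - 1` (may be empty, giving
#'   the degenerate single-vector weight 1).
#' @return Probability vector of length `m` summing to 1.
#' @export
softmax_probs <- function(lambdas) {
  z <- c(lambdas, 0)
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

#' MCMC settings for the BMA sampler
#'
#' Defaults follow the study protocol: two chains, 1000 burn-in and 1000
#' kept iterations, normal priors with SD 1000 on all parameters, normal
#' proposal SDs 0.2 for `kappa`, 1 for `alpha` and `beta`, 2 for the
#' `lambda` weight parameters, and `lambda` proposed in blocks of 10.
#'
#' @param n_chains number of chains (minimum 2, for the convergence
#'   diagnostic).
#' @param n_burnin discarded iterations per chain.
#' @param n_keep retained iterations per chain.
#' @param prior_sd prior SD for all parameters.
#' @param prop_sd_kappa,prop_sd_alpha,prop_sd_beta,prop_sd_lambda
#'   proposal SDs.
#' @param lambda_block block size for the `lambda` updates.
#' @param bgr_threshold flag the summary non-converged when any
#'   parameter's convergence statistic exceeds this (default 1.05).
#' @return A list of settings.
#' @export
mcmc_settings <- function(n_chains = 2L, n_burnin = 1000L, n_keep = 1000L,
                          prior_sd = 1000, prop_sd_kappa = 0.2,
                          prop_sd_alpha = 1, prop_sd_beta = 1,
                          prop_sd_lambda = 2, lambda_block = 10L,
                          bgr_threshold = 1.05) {
  if (n_chains < 2L) stop("at least two chains are required")
  list(n_chains = as.integer(n_chains), n_burnin = as.integer(n_burnin),
       n_keep = as.integer(n_keep), prior_sd = prior_sd,
       prop_sd_kappa = prop_sd_kappa, prop_sd_alpha = prop_sd_alpha,
       prop_sd_beta = prop_sd_beta, prop_sd_lambda = prop_sd_lambda,
       lambda_block = as.integer(lambda_block),
       bgr_threshold = bgr_threshold)
}

#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' Computes the potential scale reduction factor from the second half of
#' each chain's retained draws: with `M` chain segments of length `N`,
#' within-chain variance `W`, between-chain variance of the segment means
#' `B/N`, and pooled variance estimate `V = (N-1)/N W + B/N (1 + 1/M)`,
#' the statistic is `sqrt(V / W)`.  Values near 1 indicate convergence.
#'
#' @param draws matrix of posterior draws, iterations x chains.
#' @return The scale reduction factor (scalar >= ~1).
#' @export
bgr_psrf <- function(draws) {
  draws <- as.matrix(draws)
  n <- nrow(draws)
  half <- draws[(floor(n / 2) + 1):n, , drop = FALSE]
  N <- nrow(half); M <- ncol(half)
  means <- colMeans(half)
  W <- mean(apply(half, 2L, var))
  if (W == 0) return(1)
  B_over_N <- var(means)
  V <- (N - 1) / N * W + B_over_N * (1 + 1 / M)
  sqrt(V / W)
}

#' Quasi-2DMC with Bayesian model averaging
#'
#' Samples the mixture posterior of the Poisson linear relative-risk
#' parameters over the ensemble of `m` candidate dose vectors.
#' Alternating Metropolis-Hastings updates are applied to (a) the model
#' parameters `kappa, alpha[, beta]` against the mixture likelihood
#' `sum_k p_k L(theta; dose vector k)` given the current weights and (b)
#' the softmax weight parameters `lambda` (in fixed sequential blocks)
#' given the current model parameters.  All parameters have N(0, 1000^2)
#' priors; the intercept `kappa` is a free parameter of the fit.
#' Proposals that make every mixture component's relative risk
#' non-positive have posterior density zero and are rejected.
#'
#' @inheritParams fit_unadjusted
#' @param settings an [mcmc_settings()] list.
#' @param rng_seed optional integer seed.
#' @return An object of class `"posterior_summary"`: per-parameter
#'   posterior mean, median and equal-tailed 95% credible interval,
#'   per-parameter convergence statistic (`bgr`), per-block acceptance
#'   rates, chain sizes, and a `converged` flag (`FALSE` when any `bgr`
#'   exceeds the threshold).
#' @export
quasi_2dmc_bma <- function(meta_data, form = c("linear-quadratic", "linear"),
                           settings = mcmc_settings(), rng_seed = NULL) {
  form <- match.arg(form)
  gd <- vector_grouped_data(meta_data)
  if (!is.null(rng_seed)) set.seed(rng_seed)
  quad <- form == "linear-quadratic"
  dv <- gd$dose_vectors

  ## initialise at the regression-calibration MLE
  init_fit <- fit_linear_rr(gd, dose = colMeans(dv), form = form, ci = FALSE)
  init <- c(init_fit$kappa, init_fit$alpha, if (quad) init_fit$beta)

  res <- cpp_bma_sampler(
    gd$cases, gd$offsets, dv, quad, init,
    settings$n_burnin, settings$n_keep, settings$n_chains,
    settings$prior_sd,
    c(settings$prop_sd_kappa, settings$prop_sd_alpha, settings$prop_sd_beta),
    settings$prop_sd_lambda, settings$lambda_block)

  par_names <- c("kappa", "alpha", if (quad) "beta")
  n_par <- length(par_names)
  chains <- lapply(res$chains, function(ch) {
    colnames(ch) <- par_names
    ch
  })
  pooled <- do.call(rbind, chains)
  summ <- lapply(seq_len(n_par), function(p) {
    x <- pooled[, p]
    c(mean = mean(x), median = median(x),
      lower = unname(quantile(x, 0.025)),
      upper = unname(quantile(x, 0.975)))
  })
  names(summ) <- par_names
  bgr <- vapply(seq_len(n_par), function(p)
    bgr_psrf(sapply(chains, function(ch) ch[, p])), numeric(1))
  names(bgr) <- par_names
  acc <- colMeans(res$acceptance)
  names(acc) <- c(par_names, "lambda")

  structure(
    list(summary = summ, bgr = bgr, acceptance_rates = acc,
         n_burnin = settings$n_burnin, n_keep = settings$n_keep,
         n_chains = settings$n_chains, form = form,
         converged = all(bgr <= settings$bgr_threshold),
         chains = chains, method_tag = "bma"),
    class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf("Quasi-2DMC BMA posterior (%s form, %d chains x %d kept)\n",
              x$form, x$n_chains, x$n_keep))
  for (p in names(x$summary)) {
    s <- x$summary[[p]]
    cat(sprintf("  %-5s mean %.4g, median %.4g, 95%% CrI (%.4g, %.4g), BGR %.3f\n",
                p, s[["mean"]], s[["median"]], s[["lower"]], s[["upper"]],
                x$bgr[[p]]))
  }
  cat(sprintf("  acceptance: %s; converged: %s\n",
              paste(sprintf("%s %.2f", names(x$acceptance_rates),
                            x$acceptance_rates), collapse = ", "),
              x$converged))
  invisible(x)
}

#' @export
as_record.posterior_summary <- function(x, ...) {
  quad <- "beta" %in% names(x$summary)
  data.frame(...,
             method = "bma",
             alpha = x$summary$alpha[["mean"]],
             alpha_lo = x$summary$alpha[["lower"]],
             alpha_hi = x$summary$alpha[["upper"]],
             beta = if (quad) x$summary$beta[["mean"]] else NA_real_,
             beta_lo = if (quad) x$summary$beta[["lower"]] else NA_real_,
             beta_hi = if (quad) x$summary$beta[["upper"]] else NA_real_,
             kappa = x$summary$kappa[["mean"]],
             loglik = NA_real_, aic = NA_real_,
             converged = x$converged, bgr_max = max(x$bgr),
             stringsAsFactors = FALSE)
}

#' Dump MCMC chains to CSV for external diagnostics
#'
#' @param x a `"posterior_summary"` with retained chains.
#' @param path output file.
#' @return The path, invisibly.
#' @export
export_chains <- function(x, path) {
  stopifnot(inherits(x, "posterior_summary"))
  dfs <- lapply(seq_along(x$chains), function(c) {
    df <- as.data.frame(x$chains[[c]])
    df$chain <- c
    df$iteration <- seq_len(nrow(df))
    df
  })
  write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}
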