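# Independent oracles used across the suite.  These deliberately avoid the
# package's own likelihood code paths.

# Poisson log-likelihood via stats::dpois, with the y! constant restored so
# it is comparable to the package's constant-dropped form.
oracle_loglik <- function(y, off, dose, alpha, beta, kappa) {
  mu <- exp(kappa) * off * (1 + alpha * dose + beta * dose^2)
  sum(dpois(y, mu, log = TRUE)) + sum(lfactorial(y))
}

# small 5-group dataset with a clear dose-response, used as a fixed fixture
toy_grouped <- function() {
  structure(
    list(cases = c(95L, 20L, 52L, 48L, 35L),
         offsets = c(700, 110, 130, 40, 17),
         calibrated_dose = c(0.02, 0.12, 0.45, 1.5, 2.0),
         dose_vectors = NULL, dose_choice = "mean-true"),
    class = "grouped_data")
}

# dense grid-search maximiser of the linear-quadratic profile likelihood
grid_search_lq <- function(gd, alphas, betas) {
  best <- c(ll = -Inf, alpha = NA, beta = NA)
  for (a in alphas) for (b in betas) {
    rr <- 1 + a * gd$calibrated_dose + b * gd$calibrated_dose^2
    if (any(rr <= 0)) next
    ek <- sum(gd$cases) / sum(gd$offsets * rr)
    ll <- sum(gd$cases * log(ek * gd$offsets * rr)) - sum(gd$cases)
    if (ll > best[["ll"]]) best <- c(ll = ll, alpha = a, beta = b)
  }
  best
}

# fine scan of a profile log-likelihood: the set of coefficient values
# within qchisq(.95,1)/2 of the maximum
scan_interval <- function(prof, from, to, step = 1e-4) {
  xs <- seq(from, to, by = step)
  ll <- vapply(xs, prof, numeric(1))
  keep <- ll >= max(ll) - qchisq(0.95, 1) / 2
  range(xs[keep])
}

# dense numerical integration of the two-vector mixture posterior used as
# the MCMC oracle: parameters (kappa, alpha, lambda1), linear form,
# independent N(0, prior_sd^2) priors on all three
quadrature_mixture_posterior <- function(gd, prior_sd,
                                         kappa_grid, alpha_grid,
                                         lambda_grid) {
  stopifnot(nrow(gd$dose_vectors) == 2L)
  y <- gd$cases; off <- gd$offsets
  loglik_grid <- function(d) {
    outer(kappa_grid, alpha_grid, function(k, a) {
      ll <- 0
      for (g in seq_along(y)) {
        mu <- exp(k) * off[g] * (1 + a * d[g])
        ll <- ll + ifelse(mu > 0, y[g] * log(mu) - mu, -Inf)
      }
      ll
    })
  }
  L1 <- loglik_grid(gd$dose_vectors[1L, ])
  L2 <- loglik_grid(gd$dose_vectors[2L, ])
  prior_ka <- outer(dnorm(kappa_grid, 0, prior_sd, log = TRUE),
                    dnorm(alpha_grid, 0, prior_sd, log = TRUE), `+`)
  mx <- max(pmax(L1, L2) + prior_ka)
  post <- matrix(0, length(kappa_grid), length(alpha_grid))
  for (l in lambda_grid) {
    p1 <- exp(l) / (1 + exp(l))
    wl <- dnorm(l, 0, prior_sd)
    post <- post + wl *
      (p1 * exp(L1 + prior_ka - mx) + (1 - p1) * exp(L2 + prior_ka - mx))
  }
  Z <- sum(post)
  list(mean_alpha = sum(post * rep(alpha_grid, each = length(kappa_grid))) / Z,
       mean_kappa = sum(post * kappa_grid) / Z,
       var_alpha = sum(post * rep(alpha_grid,
                                  each = length(kappa_grid))^2) / Z -
         (sum(post * rep(alpha_grid, each = length(kappa_grid))) / Z)^2)
}
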