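gd <- toy_grouped()

test_that("the grouped log-likelihood matches an independent dpois oracle", {
  pars <- list(c(3, 0, -2), c(0.25, 2, -1.5), c(1.2, 0.4, 0))
  for (p in pars) {
    mod <- risk_model(alpha = p[1L], beta = p[2L], kappa = p[3L])
    expect_equal(
      loglik_linear_rr(gd, model = mod, form = "linear-quadratic"),
      oracle_loglik(gd$cases, gd$offsets, gd$calibrated_dose,
                    p[1L], p[2L], p[3L]),
      tolerance = 1e-10)
  }
  ## the linear form is exactly the quadratic form with beta = 0
  expect_equal(
    loglik_linear_rr(gd, model = risk_model(2, beta = 5, kappa = -1),
                     form = "linear"),
    loglik_linear_rr(gd, model = risk_model(2, beta = 0, kappa = -1),
                     form = "linear-quadratic"))
  expect_error(
    loglik_linear_rr(gd, model = risk_model(-3, 0, 0), form = "linear"),
    "non-positive")
})

test_that("the likelihood is maximised at the truth on expected data", {
  ## y set exactly to mu at (alpha, beta) = (0.8, 1.1): the log-likelihood
  ## at the truth dominates any perturbation on a test grid
  d <- gd$calibrated_dose
  mu <- exp(-1) * gd$offsets * (1 + 0.8 * d + 1.1 * d^2)
  gde <- gd; gde$cases <- mu
  ll0 <- loglik_linear_rr(gde, model = risk_model(0.8, 1.1, -1),
                          form = "linear-quadratic")
  for (da in c(-0.3, 0.2)) for (db in c(-0.4, 0.3)) {
    mod <- risk_model(0.8 + da, 1.1 + db, -1)
    k_hat <- log(sum(mu) / sum(gde$offsets *
                                 (1 + mod$alpha * d + mod$beta * d^2)))
    mod$kappa <- k_hat
    expect_lt(loglik_linear_rr(gde, model = mod, form = "linear-quadratic"),
              ll0)
  }
})

test_that("maximum-likelihood fits agree with a dense grid search", {
  fit <- fit_linear_rr(gd, form = "linear-quadratic", ci = FALSE)
  expect_true(fit$converged)
  gs <- grid_search_lq(gd, alphas = seq(-0.5, 6, by = 0.01),
                       betas = seq(-0.5, 4, by = 0.01))
  expect_equal(fit$alpha, gs[["alpha"]], tolerance = 0.02)
  expect_equal(fit$beta, gs[["beta"]], tolerance = 0.02)
  expect_gte(fit$loglik, gs[["ll"]] - 1e-6)
  expect_equal(fit$aic, -2 * fit$loglik + 6)

  flin <- fit_linear_rr(gd, form = "linear", ci = FALSE)
  expect_equal(flin$aic, -2 * flin$loglik + 4)
  ## adding the quadratic term never decreases the maximised log-likelihood
  expect_gte(fit$loglik, flin$loglik - 1e-8)
})

test_that("parameters are recovered from large simulated counts", {
  grid <- default_dose_grid(n_total = 2000L)
  meta <- simulate_meta(grid, error_spec(), risk_model(alpha = 3),
                        m = 5L, n_cases = 50000L, rng_seed = 31)
  f <- fit_linear_rr(meta$rc_data, form = "linear", ci = TRUE)
  expect_equal(f$alpha, 3, tolerance = 0.05)
  ## asymptotic regime: profile interval close to the Wald interval built
  ## from a finite-difference Hessian of the profile log-likelihood
  h <- 1e-4
  prof <- function(a)
    sharederr:::ll_profile_kappa(meta$rc_data$cases, meta$rc_data$offsets,
                                 meta$rc_data$calibrated_dose, a, 0)
  d2 <- (prof(f$alpha + h) - 2 * prof(f$alpha) + prof(f$alpha - h)) / h^2
  se <- sqrt(-1 / d2)
  wald <- f$alpha + c(-1, 1) * 1.96 * se
  expect_equal(diff(f$ci_alpha), diff(wald), tolerance = 0.1 * diff(wald))
  expect_equal(mean(f$ci_alpha), mean(wald), tolerance = 0.05 * diff(wald))
})

test_that("profile intervals match a fine likelihood scan", {
  fit <- fit_linear_rr(gd, form = "linear")
  expect_true(fit$ci_alpha[1L] <= fit$alpha && fit$alpha <= fit$ci_alpha[2L])
  prof <- function(a)
    sharederr:::ll_profile_kappa(gd$cases, gd$offsets, gd$calibrated_dose,
                                 a, 0)
  sc <- scan_interval(prof, fit$alpha - 3, fit$alpha + 4, step = 1e-4)
  expect_equal(fit$ci_alpha[1L], sc[1L], tolerance = 5e-4)
  expect_equal(fit$ci_alpha[2L], sc[2L], tolerance = 5e-4)

  fq <- fit_linear_rr(gd, form = "linear-quadratic")
  expect_true(all(is.finite(fq$ci_beta)))
  expect_true(fq$ci_beta[1L] <= fq$beta && fq$beta <= fq$ci_beta[2L])
})

test_that("degenerate grouped inputs are handled per the contract", {
  ## all cases in one group: still a finite (possibly boundary) optimum
  gd1 <- gd
  gd1$cases <- c(250L, 0L, 0L, 0L, 0L)
  f <- fit_linear_rr(gd1, form = "linear")
  expect_true(is.finite(f$alpha) && is.finite(f$loglik))

  ## all doses equal: slope unidentifiable, explicit error
  gd2 <- gd
  gd2$calibrated_dose <- rep(0.5, 5)
  expect_error(fit_linear_rr(gd2, form = "linear"), "unidentifiable")

  ## no cases at all
  gd3 <- gd
  gd3$cases <- rep(0L, 5)
  expect_error(fit_linear_rr(gd3, form = "linear"), "at least one case")
})

test_that("rescaling offsets shifts the intercept but not the slopes", {
  f1 <- fit_linear_rr(gd, form = "linear-quadratic", ci = FALSE)
  gd10 <- gd
  gd10$offsets <- gd$offsets * 10
  f2 <- fit_linear_rr(gd10, form = "linear-quadratic", ci = FALSE)
  expect_equal(f2$alpha, f1$alpha, tolerance = 1e-5)
  expect_equal(f2$beta, f1$beta, tolerance = 1e-5)
  expect_equal(f2$kappa, f1$kappa - log(10), tolerance = 1e-6)
})
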