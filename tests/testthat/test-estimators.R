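grid_est <- default_dose_grid(n_total = 200L)

meta_zero <- simulate_meta(grid_est, error_spec(), risk_model(alpha = 3),
                           m = 20L, rng_seed = 100)

test_that("with zero error all calibrated estimators coincide", {
  f_un <- fit_unadjusted(meta_zero, "linear")
  f_rc <- fit_regression_calibration(meta_zero, "linear")
  f_mc <- fit_mcml(meta_zero, "linear")
  ## surrogate = true = central dose, so the unadjusted and calibrated
  ## fits are the same fit
  expect_equal(f_un$alpha, f_rc$alpha, tolerance = 1e-6)
  expect_equal(f_un$ci_alpha, f_rc$ci_alpha, tolerance = 1e-5)
  ## the degenerate mixture collapses MCML onto regression calibration
  expect_equal(f_mc$alpha, f_rc$alpha, tolerance = 1e-5)
  expect_equal(f_mc$ci_alpha, f_rc$ci_alpha, tolerance = 1e-3)

  f_fma <- fma(meta_zero, "linear", rng_seed = 101)
  se_mc <- sd(f_fma$samples$alpha$value) /
    sqrt(nrow(f_fma$samples$alpha))
  expect_equal(f_fma$central[["alpha"]], f_rc$alpha,
               tolerance = max(4 * se_mc, 0.02))

  post <- quasi_2dmc_bma(meta_zero, "linear", rng_seed = 102)
  expect_equal(post$summary$alpha[["median"]], f_rc$alpha, tolerance = 0.25)
  expect_true(all(post$bgr < 1.05))
})

test_that("MCML with a single dose vector equals the plain fit", {
  meta1 <- simulate_meta(grid_est, error_spec(0.3, 0.3), risk_model(3),
                         m = 1L, rng_seed = 103)
  f_mc <- fit_mcml(meta1, "linear")
  f_pl <- fit_linear_rr(meta1$vector_data,
                        dose = meta1$vector_data$dose_vectors[1L, ],
                        form = "linear")
  expect_equal(f_mc$alpha, f_pl$alpha, tolerance = 1e-4)
  expect_equal(f_mc$loglik, f_pl$loglik, tolerance = 1e-6)
  expect_equal(f_mc$ci_alpha, f_pl$ci_alpha, tolerance = 5e-3)
})

test_that("FMA weights are uniform at equal AICs and track fit quality", {
  f <- fma(meta_zero, "linear", rng_seed = 104)
  ## identical dose vectors: exactly uniform weights
  expect_lt(max(abs(f$aic_weights - 1 / length(f$aic_weights))), 1e-12)
  expect_equal(sum(f$aic_weights), 1, tolerance = 1e-12)
  expect_identical(nrow(f$samples$alpha), length(f$aic_weights) * 100L)

  ## distinct vectors: lower AIC must get the larger weight under the
  ## corrected negative sign; the misprinted positive sign reverses this
  meta_b <- simulate_meta(grid_est, error_spec(0.5, 0.5), risk_model(3),
                          m = 15L, rng_seed = 105)
  fb <- fma(meta_b, "linear", rng_seed = 106)
  aics <- fb$fits$aic
  expect_gt(fb$aic_weights[which.min(aics)],
            fb$aic_weights[which.max(aics)])
  w_wrong <- exp((aics - max(aics)) / 2)
  w_wrong <- w_wrong / sum(w_wrong)
  expect_gt(w_wrong[which.max(aics)], w_wrong[which.min(aics)])
})

test_that("FMA SD recovery uses the shorter profile-CI arm", {
  f <- fit_linear_rr(meta_zero$rc_data, form = "linear")
  rec <- sharederr:::recovered_sd(f$alpha, f$ci_alpha, symmetric = TRUE)
  expect_equal(rec$sd,
               min(f$alpha - f$ci_alpha[1L], f$ci_alpha[2L] - f$alpha) / 1.96)
  rec2 <- sharederr:::recovered_sd(f$alpha, f$ci_alpha, symmetric = FALSE)
  expect_equal(rec2$sd_lower, (f$alpha - f$ci_alpha[1L]) / 1.96)
  expect_equal(rec2$sd_upper, (f$ci_alpha[2L] - f$alpha) / 1.96)
  ## the asymmetric variant runs end-to-end when asked for
  fa <- fma(meta_zero, "linear", rng_seed = 107, symmetric_sd = FALSE)
  expect_true(is.finite(fa$central[["alpha"]]))
})

test_that("weighted centiles honour the weights", {
  x <- c(1, 2, 3, 4)
  w <- c(0.97, 0.01, 0.01, 0.01)
  ## cumulative weights are (.97, .98, .99, 1): the 97.5th centile is the
  ## first value whose cumulative weight reaches 0.975
  q <- sharederr:::weighted_quantile(x, w, c(0.025, 0.5, 0.975))
  expect_equal(q, c(1, 1, 2))
  expect_equal(sharederr:::weighted_quantile(x, rep(0.25, 4), 0.99), 4)
})

test_that("the estimator registry accepts and exposes plug-ins", {
  expect_setequal(
    intersect(estimator_names(),
              c("unadjusted", "regression_calibration", "mcml", "bma",
                "fma")),
    c("unadjusted", "regression_calibration", "mcml", "bma", "fma"))
  expect_error(register_estimator("mcml", function(...) NULL), "built-in")
  register_estimator("erc_stub", function(meta, form, settings, seed)
    fit_regression_calibration(meta, form))
  expect_true("erc_stub" %in% estimator_names())
  sp <- scenario_spec(error_spec(), risk_model(3), "linear", n_meta = 2L,
                      m_sub = 4L, grid = grid_est, methods = "erc_stub",
                      seed = 5L)
  r <- run_scenario(sp)
  expect_identical(nrow(r$records), 2L)
  rm("erc_stub", envir = sharederr:::.estimator_registry)
})
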