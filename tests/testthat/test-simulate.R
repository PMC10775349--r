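grid_small <- default_dose_grid(n_total = 120L)

test_that("zero error SDs give doses exactly at the central estimates", {
  ens <- simulate_dose_ensemble(grid_small, error_spec(), m = 4L,
                                rng_seed = 1)
  cent <- grid_small$central_doses[ens$group_of_individual]
  expect_equal(ens$true_doses, matrix(cent, length(cent), 4L))
  expect_equal(ens$surrogate_doses, matrix(cent, length(cent), 4L))
})

test_that("the lognormal mean-one correction holds for every component", {
  ## oracle: E exp(sigma Z - sigma^2/2) = 1, so each individual's mean dose
  ## converges to its group central dose
  m <- 4000L
  ens <- simulate_dose_ensemble(
    grid_small,
    error_spec(sigma_shared_berkson = 0.5, sigma_unshared_berkson = 0.2,
               sigma_shared_classical = 0.2, sigma_unshared_classical = 0.5),
    m = m, rng_seed = 42)
  cent <- grid_small$central_doses[ens$group_of_individual]
  for (mat in list(ens$true_doses, ens$surrogate_doses)) {
    ratio <- rowMeans(mat) / cent
    se <- apply(mat / cent, 1L, sd) / sqrt(m)
    expect_true(all(abs(ratio - 1) < 3.5 * se + 0.01))
    ## and in aggregate, tightly
    expect_equal(mean(ratio), 1, tolerance = 0.02)
  }
})

test_that("shared draws are recoverable and uniform within sub-simulations", {
  ## with no unshared Berkson error the ratio to the corrected central dose
  ## recovers exp(sigma_share * eps_j), identical for all individuals
  sB <- 0.5
  ens <- simulate_dose_ensemble(
    grid_small, error_spec(sigma_shared_berkson = sB), m = 25L, rng_seed = 9)
  cent <- grid_small$central_doses[ens$group_of_individual]
  shared <- ens$true_doses / (cent * exp(-0.5 * sB^2))
  for (j in c(1L, 13L, 25L))
    expect_lt(diff(range(shared[, j])), 1e-12)
  ## recovered eps_j are standard normal draws, distinct across sub-sims
  eps <- log(shared[1L, ]) / sB
  expect_gt(length(unique(round(eps, 10))), 20L)
})

test_that("pairwise true-dose correlation matches the lognormal closed form", {
  ## oracle: corr = (e^{s^2} - 1) / (e^{s^2 + u^2} - 1)
  cases <- list(c(s = 0.5, u = 0.2), c(s = 0.5, u = 0.5),
                c(s = 0.2, u = 0.5))
  for (cs in cases) {
    theory <- (exp(cs[["s"]]^2) - 1) / (exp(cs[["s"]]^2 + cs[["u"]]^2) - 1)
    ens <- simulate_dose_ensemble(
      grid_small, error_spec(sigma_shared_berkson = cs[["s"]],
                             sigma_unshared_berkson = cs[["u"]]),
      m = 2000L, rng_seed = 5)
    r <- true_dose_correlation(ens, n_pairs = 150L, rng_seed = 2)
    expect_equal(r, unname(theory), tolerance = 0.03)
  }
  ## no unshared component: exactly 1
  ens1 <- simulate_dose_ensemble(
    grid_small, error_spec(sigma_shared_berkson = 0.5), m = 50L,
    rng_seed = 5)
  expect_equal(true_dose_correlation(ens1, rng_seed = 2), 1,
               tolerance = 1e-12)
  ## no shared component: near zero
  ens0 <- simulate_dose_ensemble(
    grid_small, error_spec(sigma_unshared_berkson = 0.5), m = 2000L,
    rng_seed = 5)
  expect_lt(abs(true_dose_correlation(ens0, n_pairs = 150L, rng_seed = 2)),
            0.05)
  expect_error(true_dose_correlation(
    simulate_dose_ensemble(grid_small, error_spec(), 2L)), "at least 3")
})

test_that("case generation conserves totals and matches the multinomial law", {
  model <- risk_model(alpha = 3)
  ens <- simulate_dose_ensemble(grid_small,
                                error_spec(sigma_shared_berkson = 0.2),
                                m = 50L, rng_seed = 3)
  cases <- simulate_cases(ens, model, n_cases = 250L, rng_seed = 4)
  expect_identical(sum(cases), 250L)
  expect_true(all(cases >= 0L))

  ## goodness of fit of group totals against the analytic probabilities,
  ## re-derived here from the ensemble matrices (independent of the
  ## package's internals)
  rr <- 1 + model$alpha * rowMeans(ens$true_doses)
  p_group <- as.vector(rowsum(rr / sum(rr), ens$group_of_individual))
  tot <- rep(0, grid_small$n_groups)
  n_rep <- 60L
  for (s in seq_len(n_rep)) {
    cs <- simulate_cases(ens, model, n_cases = 250L, rng_seed = 1000 + s)
    tot <- tot + as.vector(rowsum(as.numeric(cs), ens$group_of_individual))
  }
  chi <- sum((tot - n_rep * 250 * p_group)^2 / (n_rep * 250 * p_group))
  expect_gt(pchisq(chi, df = grid_small$n_groups - 1L, lower.tail = FALSE),
            1e-3)

  ## null model: uniform probabilities over individuals
  cases0 <- simulate_cases(ens, risk_model(alpha = 0), 10000L, rng_seed = 6)
  grp0 <- as.vector(rowsum(as.numeric(cases0), ens$group_of_individual))
  expect_equal(grp0 / 10000,
               grid_small$n_individuals / sum(grid_small$n_individuals),
               tolerance = 0.05)

  ## negative relative risk is rejected with the offending dose named
  expect_error(simulate_cases(ens, risk_model(alpha = -5)),
               "non-positive relative risk")
})

test_that("collapsing to groups conserves cases and selects the right dose", {
  ens <- simulate_dose_ensemble(
    grid_small, error_spec(0.2, 0.2, 0.2, 0.2), m = 30L, rng_seed = 8)
  cases <- simulate_cases(ens, risk_model(alpha = 3), 250L, rng_seed = 9)

  rc <- collapse_to_groups(ens, cases, "mean-true")
  expect_identical(sum(rc$cases), 250L)
  expect_equal(rc$cases,
               as.integer(rowsum(as.numeric(cases),
                                 ens$group_of_individual)[, 1L]))
  expect_equal(rc$offsets, grid_small$person_years)
  ## mean-true dose equals the group mean over individuals x sub-sims
  g1 <- ens$group_of_individual == 1L
  expect_equal(rc$calibrated_dose[1L], mean(ens$true_doses[g1, ]))

  un <- collapse_to_groups(ens, cases, "single-surrogate-draw",
                           surrogate_draw = 3L)
  expect_equal(un$calibrated_dose[1L], mean(ens$surrogate_doses[g1, 3L]))

  pv <- collapse_to_groups(ens, cases, "per-subsim-vectors")
  expect_identical(dim(pv$dose_vectors), c(30L, 5L))
  expect_true(all(pv$dose_vectors > 0))
  expect_equal(pv$dose_vectors[3L, 1L], mean(ens$true_doses[g1, 3L]))

  ## zero-error ensembles: every dose summary equals the central doses and
  ## all m vectors are identical
  ens0 <- simulate_dose_ensemble(grid_small, error_spec(), m = 6L,
                                 rng_seed = 1)
  pv0 <- collapse_to_groups(ens0, cases, "per-subsim-vectors")
  expect_equal(pv0$calibrated_dose, grid_small$central_doses)
  for (j in 2:6)
    expect_equal(pv0$dose_vectors[j, ], pv0$dose_vectors[1L, ])

  expect_error(collapse_to_groups(ens, cases[-1], "mean-true"),
               "one entry per individual")
})

test_that("identical seeds reproduce ensembles and meta-simulations exactly", {
  e <- error_spec(0.5, 0.2, 0.2, 0.2)
  a <- simulate_dose_ensemble(grid_small, e, m = 10L, rng_seed = 11)
  b <- simulate_dose_ensemble(grid_small, e, m = 10L, rng_seed = 11)
  expect_identical(a$true_doses, b$true_doses)
  expect_identical(a$surrogate_doses, b$surrogate_doses)

  m1 <- simulate_meta(grid_small, e, risk_model(alpha = 3), m = 10L,
                      rng_seed = 12)
  m2 <- simulate_meta(grid_small, e, risk_model(alpha = 3), m = 10L,
                      rng_seed = 12)
  expect_identical(m1$cases_by_group, m2$cases_by_group)
  expect_identical(m1$vector_data$dose_vectors, m2$vector_data$dose_vectors)
})

test_that("ensembles export to long-format CSV", {
  ens <- simulate_dose_ensemble(grid_small, error_spec(0.2), m = 3L,
                                rng_seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  export_ensemble(ens, path, meta_id = 7L)
  df <- read.csv(path)
  expect_identical(nrow(df), 120L * 3L)
  expect_named(df, c("meta_id", "sub_id", "individual_id", "group",
                     "true_dose", "surrogate_dose"))
  expect_equal(df$true_dose[df$sub_id == 2L],
               unname(ens$true_doses[, 2L]))
})
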