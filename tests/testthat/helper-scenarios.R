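# Lazily computed, cached scenario ensembles shared by the acceptance
# tests (several criteria read different summaries of the same ensemble).

.scenario_cache <- new.env(parent = emptyenv())

cached_scenario <- function(key, maker) {
  if (!exists(key, envir = .scenario_cache))
    assign(key, maker(), envir = .scenario_cache)
  get(key, envir = .scenario_cache)
}

# linear model, zero Berkson error, classical 20%/20% (the tabulated
# first-row scenario), n_meta = 200
linear_row1_run <- function() cached_scenario("lin_row1", function() {
  spec <- scenario_spec(
    errors = error_spec(0, 0, 0.2, 0.2),
    truth = risk_model(alpha = 3), form = "linear",
    n_meta = 200L, m_sub = 100L,
    methods = c("unadjusted", "regression_calibration", "bma"),
    seed = 20240313L, name = "linear_b0_b0")
  run_scenario(spec)
})

# linear model, unshared Berkson 20% / shared Berkson 50%, FMA
linear_2050_fma_run <- function() cached_scenario("lin_2050", function() {
  spec <- scenario_spec(
    errors = error_spec(sigma_shared_berkson = 0.5,
                        sigma_unshared_berkson = 0.2,
                        sigma_shared_classical = 0.2,
                        sigma_unshared_classical = 0.2),
    truth = risk_model(alpha = 3), form = "linear",
    n_meta = 100L, m_sub = 100L, methods = "fma",
    seed = 4180L, name = "linear_b20_b50")
  run_scenario(spec)
})

# linear-quadratic model, shared and unshared Berkson 50%, BMA
lq_5050_bma_run <- function() cached_scenario("lq_5050", function() {
  spec <- scenario_spec(
    errors = error_spec(sigma_shared_berkson = 0.5,
                        sigma_unshared_berkson = 0.5,
                        sigma_shared_classical = 0.2,
                        sigma_unshared_classical = 0.2),
    truth = risk_model(alpha = 0.25, beta = 2), form = "linear-quadratic",
    n_meta = 100L, m_sub = 100L, methods = "bma",
    seed = 55019L, name = "lq_b50_b50")
  run_scenario(spec)
})

# linear-quadratic model, unshared 20% / shared 50%, FMA
lq_2050_fma_run <- function() cached_scenario("lq_2050", function() {
  spec <- scenario_spec(
    errors = error_spec(sigma_shared_berkson = 0.5,
                        sigma_unshared_berkson = 0.2,
                        sigma_shared_classical = 0.2,
                        sigma_unshared_classical = 0.2),
    truth = risk_model(alpha = 0.25, beta = 2), form = "linear-quadratic",
    n_meta = 100L, m_sub = 100L, methods = "fma",
    seed = 2050L, name = "lq_b20_b50")
  run_scenario(spec)
})

# linear-quadratic model, zero Berkson, regression calibration (ERR bias)
lq_00_rc_run <- function() cached_scenario("lq_00", function() {
  spec <- scenario_spec(
    errors = error_spec(0, 0, 0.2, 0.2),
    truth = risk_model(alpha = 0.25, beta = 2), form = "linear-quadratic",
    n_meta = 200L, m_sub = 100L, methods = "regression_calibration",
    seed = 7342L, name = "lq_b0_b0")
  run_scenario(spec)
})

# standard error of an ensemble mean
mean_se <- function(x) sd(x) / sqrt(length(x))

# 3-sigma binomial half-width (percentage points) around coverage p_pct
binom_tol <- function(p_pct, n) 3 * sqrt(p_pct / 100 * (1 - p_pct / 100) / n) * 100
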