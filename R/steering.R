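## Steering-file workflow: one YAML file describes a whole study (grid,
## true model, error scenarios, estimators, ensemble sizes, seeds) and is
## validated fully before any computation.

steering_top_keys <- c("name", "grid", "truth", "form", "scenarios",
                       "methods", "n_meta", "m_sub", "n_cases", "seed",
                       "mcmc", "fma", "output_dir")
steering_grid_keys <- c("edges", "central_doses", "person_years",
                        "n_individuals", "n_total")
steering_scenario_keys <- c("name", "sigma_shared_berkson",
                            "sigma_unshared_berkson",
                            "sigma_shared_classical",
                            "sigma_unshared_classical")
steering_mcmc_keys <- c("n_chains", "n_burnin", "n_keep", "prior_sd",
                        "prop_sd_kappa", "prop_sd_alpha", "prop_sd_beta",
                        "prop_sd_lambda", "lambda_block", "bgr_threshold")
steering_fma_keys <- c("k", "symmetric_sd")

check_keys <- function(x, allowed, where) {
  bad <- setdiff(names(x), allowed)
  if (length(bad))
    stop("unknown steering key(s) in ", where, ": ",
         paste(bad, collapse = ", "))
}

#' Read and validate a steering file
#'
#' Parses a YAML steering file describing a complete study and validates
#' it fully -- unknown keys anywhere are rejected and every scenario must
#' expand to a valid [scenario_spec()] -- before anything is computed.
#'
#' @param path steering file path.
#' @return An object of class `"steering_config"`: the validated
#'   configuration with a `specs` element holding one [scenario_spec()]
#'   per scenario.
#' @export
read_steering <- function(path) {
  if (!file.exists(path)) stop("steering file not found: ", path)
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, steering_top_keys, "top level")
  for (req in c("truth", "form", "scenarios", "methods", "n_meta",
                "m_sub", "seed"))
    if (is.null(cfg[[req]])) stop("steering key '", req, "' is required")

  grid <- if (is.null(cfg$grid)) default_dose_grid() else {
    check_keys(cfg$grid, steering_grid_keys, "grid")
    if (!is.null(cfg$grid$edges)) {
      edges <- do.call(rbind, lapply(cfg$grid$edges, function(e) {
        e <- unlist(e)
        e[is.character(e) & e %in% c("Inf", ".inf")] <- Inf
        as.numeric(e)
      }))
      dose_grid(edges, cfg$grid$central_doses, cfg$grid$person_years,
                cfg$grid$n_individuals)
    } else default_dose_grid(n_total = cfg$grid$n_total %||% 1000L)
  }

  check_keys(cfg$truth, c("alpha", "beta", "kappa"), "truth")
  truth <- risk_model(cfg$truth$alpha, cfg$truth$beta %||% 0,
                      cfg$truth$kappa %||% 0)
  if (!cfg$form %in% c("linear", "linear-quadratic"))
    stop("'form' must be \"linear\" or \"linear-quadratic\"")

  mcmc <- if (is.null(cfg$mcmc)) mcmc_settings() else {
    check_keys(cfg$mcmc, steering_mcmc_keys, "mcmc")
    do.call(mcmc_settings, cfg$mcmc)
  }
  fma_k <- 100L; fma_sym <- TRUE
  if (!is.null(cfg$fma)) {
    check_keys(cfg$fma, steering_fma_keys, "fma")
    fma_k <- cfg$fma$k %||% 100L
    fma_sym <- cfg$fma$symmetric_sd %||% TRUE
  }

  master_seed <- as.integer(cfg$seed)
  set.seed(master_seed)
  sc_seeds <- sample.int(.Machine$integer.max - 1L,
                         length(cfg$scenarios))
  specs <- lapply(seq_along(cfg$scenarios), function(i) {
    sc <- cfg$scenarios[[i]]
    check_keys(sc, steering_scenario_keys, sprintf("scenario %d", i))
    errors <- error_spec(
      sigma_shared_berkson = sc$sigma_shared_berkson %||% 0,
      sigma_unshared_berkson = sc$sigma_unshared_berkson %||% 0,
      sigma_shared_classical = sc$sigma_shared_classical %||% 0,
      sigma_unshared_classical = sc$sigma_unshared_classical %||% 0)
    scenario_spec(errors, truth, cfg$form,
                  n_meta = cfg$n_meta, m_sub = cfg$m_sub,
                  n_cases = cfg$n_cases %||% 250L, grid = grid,
                  methods = unlist(cfg$methods), seed = sc_seeds[i],
                  mcmc = mcmc, fma_k = fma_k, fma_symmetric_sd = fma_sym,
                  name = sc$name %||% sprintf("scenario_%d", i))
  })
  structure(list(name = cfg$name %||% "study", specs = specs,
                 master_seed = master_seed,
                 output_dir = cfg$output_dir %||% "results",
                 raw = cfg),
            class = "steering_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.steering_config <- function(x, ...) {
  cat(sprintf("Steering config '%s': %d scenario(s), master seed %d\n",
              x$name, length(x$specs), x$master_seed))
  for (s in x$specs)
    cat(sprintf("  %s: n_meta=%d m_sub=%d methods=%s\n", s$name,
                s$n_meta, s$m_sub, paste(s$methods, collapse = ",")))
  invisible(x)
}
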