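#' Deterministic small fixtures for testing and demonstration
#'
#' Generates one of three tiny, fully reproducible datasets:
#' `"toy-grouped-data"` (a 5-group case table with doses at the central
#' estimates), `"degenerate-ensemble"` (a zero-error ensemble whose doses
#' all equal the central doses), and `"two-vector-mixture"` (a 2-group
#' grouped dataset with m = 2 candidate dose vectors, small enough for
#' dense numerical integration of the mixture posterior).
#'
#' @param kind fixture kind (see above).
#' @param rng_seed integer seed (default 1).
#' @param path optional CSV path; when given the fixture is also written
#'   to disk.
#' @param n_cases total cases for `"toy-grouped-data"` (default 250).
#' @return The fixture object (a `"grouped_data"` or `"dose_ensemble"`).
#' @export
make_fixture <- function(kind = c("toy-grouped-data",
                                  "degenerate-ensemble",
                                  "two-vector-mixture"),
                         rng_seed = 1L, path = NULL, n_cases = 250L) {
  kind <- match.arg(kind)
  set.seed(rng_seed)
  obj <- switch(kind,
    "toy-grouped-data" = {
      grid <- default_dose_grid(n_total = 100L)
      ens <- simulate_dose_ensemble(grid, error_spec(), m = 1L)
      cases <- simulate_cases(ens, risk_model(alpha = 3), n_cases)
      collapse_to_groups(ens, cases, "mean-true")
    },
    "degenerate-ensemble" = {
      grid <- default_dose_grid(n_total = 50L)
      simulate_dose_ensemble(grid, error_spec(), m = 5L)
    },
    "two-vector-mixture" = {
      gd <- structure(
        list(cases = c(14L, 26L), offsets = c(100, 50),
             calibrated_dose = c(0.25, 1.25),
             dose_vectors = rbind(c(0.2, 1.0), c(0.3, 1.5)),
             dose_choice = "per-subsim-vectors"),
        class = "grouped_data")
      gd
    })
  if (!is.null(path)) {
    df <- switch(kind,
      "toy-grouped-data" = data.frame(group = seq_along(obj$cases),
                                      cases = obj$cases,
                                      offset = obj$offsets,
                                      dose = obj$calibrated_dose),
      "degenerate-ensemble" = data.frame(
        individual = rep(seq_len(nrow(obj$true_doses)), obj$m),
        sub_id = rep(seq_len(obj$m), each = nrow(obj$true_doses)),
        group = rep(obj$group_of_individual, obj$m),
        true_dose = as.vector(obj$true_doses),
        surrogate_dose = as.vector(obj$surrogate_doses)),
      "two-vector-mixture" = data.frame(
        group = rep(1:2, times = 3),
        what = rep(c("data", "vector1", "vector2"), each = 2),
        cases = c(obj$cases, NA, NA, NA, NA),
        offset = c(obj$offsets, NA, NA, NA, NA),
        dose = c(obj$calibrated_dose, obj$dose_vectors[1L, ],
                 obj$dose_vectors[2L, ])))
    write.csv(df, path, row.names = FALSE)
  }
  obj
}
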