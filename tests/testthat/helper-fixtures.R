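# Shared fixtures, built once per test run.

uniform_cost <- function(n = 5, cost = 1, cell = 100) {
  raster_grid(matrix(cost, n, n), cell_size = cell)
}

# small valley landscape + truth, cached across test files
.fixture_env <- new.env()

small_landscape <- function() {
  if (is.null(.fixture_env$land)) {
    .fixture_env$land <- generate_landscape(
      landscape_config(n_rows = 120, n_cols = 120, seed = 42))
    .fixture_env$truth <- true_model()
    .fixture_env$truth_map <- simulate_truth(.fixture_env$land$stack,
                                             .fixture_env$truth)
  }
  list(land = .fixture_env$land, truth = .fixture_env$truth,
       truth_map = .fixture_env$truth_map)
}

small_survey <- function(n_sites = 150, n_occasions = 6, seed = 7) {
  fx <- small_landscape()
  simulate_surveys(fx$truth_map,
                   survey_design(n_sites = n_sites, n_occasions = n_occasions),
                   fx$truth, stack = fx$land$stack, seed = seed)
}

random_history <- function(n, T_, seed = 1, p_na = 0) {
  withr::with_seed(seed, {
    y <- matrix(rbinom(n * T_, 1, 0.35), n, T_)
    if (p_na > 0) y[runif(n * T_) < p_na] <- NA
    # every site keeps at least one surveyed occasion
    for (i in seq_len(n)) if (all(is.na(y[i, ]))) y[i, 1] <- 0
    rep_mat <- function(v) matrix(rep(v, T_), n, T_)
    structure(list(
      y = y, site_id = seq_len(n),
      occ_cov = list(
        lure = rep_mat(rbinom(n, 1, 0.5)),
        temperature = rep_mat(sample(c("low", "medium", "high"), n, TRUE)),
        camera_view = rep_mat(sample(c("open", "limited"), n, TRUE))),
      segment_days = 5), class = "detection_history")
  })
}
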