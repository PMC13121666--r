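# Shared fixtures. The reduced two-center cohort (and its full pipeline run)
# is expensive, so it is built once per test session and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture_spec <- function() {
  cohort_spec(n_gb = 32, n_sbm = 16,
              grid_shape = c(36, 36, 36), tumor_radius_range = c(6, 11),
              centers = data.frame(center = c("A", "B"),
                                   n_gb = c(24, 8), n_sbm = c(12, 4)),
              seed = 11L)
}

fixture_pipeline <- function() {
  if (is.null(.fixture_env$pipeline)) {
    cfg <- run_config(cohort = fixture_spec(), cluster_cap = 500, seed = 11L)
    .fixture_env$pipeline <- suppressWarnings(run_pipeline(cfg, verbose = FALSE))
  }
  .fixture_env$pipeline
}

# a single mid-sized case reused by feature tests
fixture_case <- function() {
  if (is.null(.fixture_env$case)) {
    spec <- cohort_spec(n_gb = 1, n_sbm = 0, grid_shape = c(32, 32, 32),
                        tumor_radius_range = c(6, 10))
    .fixture_env$case <- generate_case(spec, "GB", seed = 5)
  }
  .fixture_env$case
}
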