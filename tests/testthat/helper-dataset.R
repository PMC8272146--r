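# Shared fixtures built once per test run. The default-protocol synthetic
# dataset and the model fits on it are used by several test files; they are
# memoised here (the simulation runs at 8192 rays per pose-transmitter, the
# study-scale protocol otherwise unchanged).

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- force(expr)
  .fixtures[[name]]
}

TEST_RAYS <- 8192
DATASET_SEED <- 101
FIT_SEED <- 11

shared_dataset <- function() memo("dataset",
  simulate_bench_dataset(n_rays = TEST_RAYS, seed = DATASET_SEED))

shared_matrix <- function() memo("matrix",
  build_feature_matrix(shared_dataset()$features))

shared_gbrt_cv <- function() memo("gbrt_cv", {
  fm <- shared_matrix()
  cross_validate_gaze(fm$X, fm$Y, kind = "gbrt", seed = FIT_SEED)
})

shared_linear_cv <- function() memo("linear_cv", {
  fm <- shared_matrix()
  cross_validate_gaze(fm$X, fm$Y, kind = "linear", seed = FIT_SEED)
})

shared_gbrt_fit <- function() memo("gbrt_fit", {
  fm <- shared_matrix()
  fit_gaze(fm$X, fm$Y, kind = "gbrt", seed = FIT_SEED)
})

# a small two-pose protocol for fast structural tests
tiny_protocol <- function(sessions = 2, repeats = 10)
  protocol_spec(gaze_grid = cbind(theta_deg = c(-5, 5), phi_deg = c(0, 0)),
                repeats = repeats, sessions = sessions)
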