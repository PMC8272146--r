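test_that("group averaging takes consecutive disjoint blocks", {
  tr <- matrix(rep(1:5, each = 100), nrow = 10, ncol = 50)
  avg <- average_groups(tr, 10)
  expect_equal(ncol(avg), 5)
  expect_equal(avg, matrix(rep(1:5, each = 10), 10, 5))
  same <- matrix(7, 10, 50)
  expect_equal(average_groups(same, 10), matrix(7, 10, 5))
  expect_error(average_groups(matrix(0, 4, 47), 10), "remainder 7")

  set.seed(12)
  noise <- matrix(rnorm(1e4 * 50), ncol = 50)
  expect_equal(sd(noise) / sd(average_groups(noise, 10)), sqrt(10),
               tolerance = 0.05 * sqrt(10))
})

test_that("band-pass keeps the carrier and rejects out-of-band tones", {
  fs <- 80e6
  t <- seq(0, 50e-6, by = 1 / fs)
  mid <- function(x) x[1001:3000] # steady-state region
  inband <- sin(2 * pi * 1.74e6 * t)
  expect_gte(max(abs(mid(bandpass(inband, fs)))), 0.95)
  low <- sin(2 * pi * 0.4e6 * t)
  expect_lt(max(abs(mid(bandpass(low, fs)))), 10^(-40 / 20))
  expect_equal(bandpass(numeric(1000), fs), numeric(1000))
  expect_error(bandpass(inband, fs, low = 2e6, high = 1e6), "config error")
  expect_error(bandpass(inband, fs, high = 50e6), "config error")
  # the FFT zero-phase path matches time-domain forward-backward filtering
  set.seed(2)
  x <- rnorm(4001) * 0.05
  x[1800:2121] <- x[1800:2121] + synth_burst(burst_spec())
  expect_equal(bandpass(x, fs), bandpass(x, fs, method = "filtfilt"),
               tolerance = 0.02)
})

test_that("peak features recover constructed echoes exactly", {
  b <- burst_spec(duration_us = 200)
  fs <- b$sample_rate_hz
  arr <- data.frame(receiver_id = "rx", path_mm = 41.16, time_us = 120,
                    n_bounces = 1L, weight = 0.7)
  x <- render_trace(arr, b)
  f <- bandpass(x, fs)
  pk <- extract_peak_features(x, f, fs)
  # oracle: the raw peak sits at the burst's discrete argmax after the echo
  # delay (the 80/1.74 samples-per-cycle grid fixes which crest wins)
  wave <- synth_burst(b)
  expected <- (round(120e-6 * fs) + which.max(wave) - 1) / fs * 1e6
  expect_equal(pk[["amp"]], max(x))
  expect_lt(abs(pk[["tof_us"]] - expected), 0.5 / fs * 1e6 + 1e-9)

  # ties resolve to the first instance of the peak value
  flat <- numeric(4000)
  flat[1000] <- flat[1400] <- 1
  fflat <- numeric(4000)
  fflat[1200] <- 1
  pk2 <- extract_peak_features(flat, fflat, fs)
  expect_equal(pk2[["tof_us"]], 999 / fs * 1e6)

  # window clipping near the trace start
  early <- numeric(4000)
  early[100] <- 1
  fearly <- numeric(4000)
  fearly[120] <- 1
  pk3 <- extract_peak_features(early, fearly, fs, window_us = 45)
  expect_equal(pk3[["amp"]], 1)
  expect_error(extract_peak_features(numeric(10), numeric(10), fs),
               "degenerate")
  expect_error(extract_peak_features(numeric(10), numeric(12), fs),
               "equal length")
})

test_that("features are shift- and scale-equivariant", {
  b <- burst_spec(duration_us = 200)
  fs <- b$sample_rate_hz
  mk <- function(t_us, w = 0.5)
    render_trace(data.frame(receiver_id = "rx", path_mm = 1, time_us = t_us,
                            n_bounces = 1L, weight = w), b)
  x1 <- mk(100)
  x2 <- mk(110) # all echoes delayed by 10 us
  p1 <- extract_peak_features(x1, bandpass(x1, fs), fs)
  p2 <- extract_peak_features(x2, bandpass(x2, fs), fs)
  expect_equal(p2[["tof_us"]] - p1[["tof_us"]], 10, tolerance = 1 / 80)
  expect_equal(p2[["amp"]], p1[["amp"]], tolerance = 1e-9)
  x3 <- 3 * x1
  p3 <- extract_peak_features(x3, bandpass(x3, fs), fs)
  expect_equal(p3[["amp"]], 3 * p1[["amp"]], tolerance = 1e-9)
  expect_equal(p3[["tof_us"]], p1[["tof_us"]])
})

test_that("feature matrix has the documented layout and checks completeness", {
  fm <- shared_matrix()
  expect_equal(dim(fm$X), c(1620, 38))
  expect_equal(colnames(fm$X)[1], "tof_us_m90")
  expect_equal(colnames(fm$X)[19], "tof_us_p90")
  expect_equal(colnames(fm$X)[20], "amp_m90")
  expect_equal(nrow(unique(fm$meta[, c("theta_deg", "phi_deg")])), 36)
  expect_true(all(table(fm$meta$session) == 180))

  ds <- shared_dataset()
  one <- ds$features[ds$features$theta_deg == -5 & ds$features$phi_deg == -5 &
                       ds$features$session == 0, ]
  fm1 <- build_feature_matrix(one)
  expect_equal(nrow(fm1$X), 5)
  broken <- ds$features[-3, ]
  expect_error(build_feature_matrix(broken), "incomplete dataset")
})

test_that("pipeline is deterministic end to end", {
  ds <- shared_dataset()
  fm1 <- build_feature_matrix(ds$features)
  fm2 <- build_feature_matrix(ds$features)
  expect_identical(fm1$X, fm2$X)
})

test_that("open-eye time of flight peaks at the central transmitter", {
  proto <- protocol_spec(gaze_grid = cbind(theta_deg = 0, phi_deg = 0),
                        repeats = 10, sessions = 1)
  ds <- simulate_bench_dataset(proto, occluder = NULL, n_rays = 65536,
                               seed = 31,
                               noise = noise_spec(additive_std = 0))
  tof <- ds$features$tof_us[ds$features$k == 0]
  tx <- ds$features$tx_deg[ds$features$k == 0]
  # the arc extremes (+/-80, +/-90) carry the least energy and their peak
  # can ride a multi-bounce cluster, so the shape checks cover |tx| <= 70
  core <- abs(tx) <= 70
  expect_lte(abs(tx[core][which.max(tof[core])]), 10)
  # falls off symmetrically toward the arc ends
  left <- tof[match(-c(10, 30, 50, 70), tx)]
  right <- tof[match(c(10, 30, 50, 70), tx)]
  expect_equal(left, right, tolerance = 0.01)
  coarse <- tof[match(c(0, 30, 50, 70), tx)]
  expect_true(all(diff(coarse) < 0))
  expect_gt(tof[match(0, tx)] - tof[match(70, tx)], 1)
})
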