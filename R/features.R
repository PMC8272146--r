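# Feature engineering: group averaging of repeated traces, zero-phase
# Butterworth band-pass filtering, windowed first-peak detection, and
# assembly of the regression feature matrix.

#' Average consecutive groups of repeated traces
#'
#' Traces are averaged samplewise in consecutive disjoint blocks of
#' `group_size` in acquisition order: 50 repeats yield 5 averaged traces
#' (k = 0..4).
#'
#' @param traces Numeric matrix, one column per trace (rows are samples).
#' @param group_size Traces per block (must divide the trace count).
#' @return Matrix with one column per group, in block order.
#' @export
average_groups <- function(traces, group_size = 10) {
  traces <- as.matrix(traces)
  n <- ncol(traces)
  if (n %% group_size != 0)
    stop("trace count (", n, ") not divisible by group size (", group_size,
         "): remainder ", n %% group_size)
  k <- n / group_size
  out <- vapply(seq_len(k), function(i)
    rowMeans(traces[, ((i - 1) * group_size + 1):(i * group_size),
                    drop = FALSE]),
    numeric(nrow(traces)))
  matrix(out, nrow = nrow(traces), ncol = k)
}

# cache for filter designs and frequency-response grids
.filter_cache <- new.env(parent = emptyenv())

butter_design <- function(fs, low, high, order) {
  key <- paste(fs, low, high, order, sep = "|")
  if (is.null(.filter_cache[[key]]))
    .filter_cache[[key]] <- signal::butter(order, c(low, high) / (fs / 2),
                                           type = "pass")
  .filter_cache[[key]]
}

# |H(e^{i w})|^2 of the digital Butterworth band-pass on the length-n FFT grid
butter_mag2_grid <- function(n, fs, low, high, order) {
  key <- paste("g", n, fs, low, high, order, sep = "|")
  if (is.null(.filter_cache[[key]])) {
    bf <- butter_design(fs, low, high, order)
    w <- 2 * pi * (seq_len(n) - 1) / n
    z <- exp(-1i * w)
    H <- outer(z, seq_along(bf$b) - 1, "^") %*% bf$b /
      (outer(z, seq_along(bf$a) - 1, "^") %*% bf$a)
    .filter_cache[[key]] <- as.vector(Mod(H)^2)
  }
  .filter_cache[[key]]
}

#' Butterworth band-pass filter, zero phase
#'
#' Order-`order` Butterworth band-pass (default 1.6-1.9 MHz) applied with
#' zero phase so the filter's group delay does not bias the time-of-flight
#' estimate. `method = "fft"` (default) multiplies the spectrum by the
#' filter's magnitude-squared response — the exact steady-state
#' forward-backward (filtfilt) response, and much faster on long traces;
#' `method = "filtfilt"` runs the time-domain forward-backward filter;
#' `method = "single"` is a causal single pass.
#'
#' @param x Numeric signal.
#' @param fs Sample rate, Hz.
#' @param low,high Band edges, Hz (`0 < low < high < fs / 2`).
#' @param order Filter order (of the underlying low-pass prototype).
#' @param method `"fft"`, `"filtfilt"` or `"single"`.
#' @return Filtered signal, same length.
#' @export
bandpass <- function(x, fs, low = 1.6e6, high = 1.9e6, order = 4,
                     method = c("fft", "filtfilt", "single")) {
  method <- match.arg(method)
  if (!(low > 0 && low < high && high < fs / 2))
    stop("config error: invalid band [", low, ", ", high,
         "] for sample rate ", fs)
  if (method == "fft") {
    mag2 <- butter_mag2_grid(length(x), fs, low, high, order)
    return(Re(stats::fft(stats::fft(x) * mag2, inverse = TRUE)) / length(x))
  }
  bf <- butter_design(fs, low, high, order)
  if (method == "filtfilt") signal::filtfilt(bf, x) else
    as.numeric(signal::filter(bf, x))
}

#' Time-of-flight and amplitude from an averaged trace
#'
#' Squares the band-pass-filtered trace, locates its global maximum, centers
#' a `window_us` window there (clipped at the trace edges), and returns the
#' time of the first occurrence of the maximum of the *raw averaged* trace
#' inside that window (`tof_us`) together with that maximum value (`amp`).
#' Ties resolve to the earliest sample.
#'
#' @param raw_avg Averaged raw trace (numeric).
#' @param filtered Band-pass-filtered version of the same trace.
#' @param fs Sample rate, Hz.
#' @param window_us Window width centered on the filtered-energy peak, us.
#' @return Named numeric vector `c(tof_us, amp)`.
#' @export
extract_peak_features <- function(raw_avg, filtered, fs, window_us = 45) {
  if (length(raw_avg) != length(filtered))
    stop("raw and filtered traces must have equal length")
  f2 <- filtered^2
  if (all(f2 == 0)) stop("degenerate trace: filtered signal is all zero")
  ctr <- which.max(f2)
  half <- round(window_us / 2 * 1e-6 * fs)
  lo <- max(1L, ctr - half)
  hi <- min(length(raw_avg), ctr + half)
  seg <- raw_avg[lo:hi]
  if (all(seg == 0)) stop("degenerate trace: analysis window is all zero")
  i <- which.max(seg) # first instance of the peak value
  c(tof_us = (lo + i - 2) / fs * 1e6, amp = seg[i])
}

# canonical feature column names: tof then amp, transmitter positions sorted
feature_colnames <- function(tx_positions_deg) {
  tx <- sort(tx_positions_deg)
  lab <- ifelse(tx < 0, paste0("m", abs(tx)), paste0("p", tx))
  c(paste0("tof_us_", lab), paste0("amp_", lab))
}

#' Assemble the regression feature matrix
#'
#' Pivots the long per-(pose, session, group, transmitter) feature table to
#' one row per (pose, session, group) with columns ordered time-of-flight at
#' each transmitter position (ascending degrees) then amplitude at each
#' position, and the gaze labels. The default protocol (36 poses, 19
#' transmitter positions, 9 sessions, 5 groups) yields a 1620 x 38 matrix.
#'
#' @param features Long data.frame with columns `theta_deg`, `phi_deg`,
#'   `session`, `k`, `tx_deg`, `tof_us`, `amp` (as produced by
#'   [simulate_bench_dataset()]).
#' @return List: `X` (feature matrix), `Y` (two-column gaze matrix, degrees),
#'   `meta` (data.frame theta_deg, phi_deg, session, k per row).
#' @export
build_feature_matrix <- function(features) {
  need <- c("theta_deg", "phi_deg", "session", "k", "tx_deg", "tof_us", "amp")
  if (!all(need %in% names(features)))
    stop("missing columns: ", paste(setdiff(need, names(features)),
                                    collapse = ", "))
  tx <- sort(unique(features$tx_deg))
  key <- interaction(features$theta_deg, features$phi_deg, features$session,
                     features$k, drop = TRUE)
  cnt <- table(key)
  if (any(cnt != length(tx))) {
    bad <- names(cnt)[cnt != length(tx)]
    stop("incomplete dataset: ", length(bad),
         " (pose, session, group) cells lack some transmitter positions, ",
         "e.g. ", bad[1])
  }
  ord <- order(features$theta_deg, features$phi_deg, features$session,
               features$k, features$tx_deg)
  f <- features[ord, ]
  nrow_out <- nrow(f) / length(tx)
  tofm <- matrix(f$tof_us, ncol = length(tx), byrow = TRUE)
  ampm <- matrix(f$amp, ncol = length(tx), byrow = TRUE)
  X <- cbind(tofm, ampm)
  colnames(X) <- feature_colnames(tx)
  first <- seq(1, nrow(f), by = length(tx))
  meta <- f[first, c("theta_deg", "phi_deg", "session", "k")]
  rownames(meta) <- NULL
  Y <- as.matrix(meta[, c("theta_deg", "phi_deg")])
  list(X = X, Y = Y, meta = meta)
}
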