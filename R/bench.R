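# Bench emulation: tone-burst synthesis, trace rendering with session
# variability and measurement noise, the gaze-protocol dataset generator, and
# the attenuation / directivity characterization sweeps.

#' Tone-burst specification
#'
#' The probe signal: a train of `n_cycles` sinusoid oscillations at
#' `carrier_hz` (default 7 cycles at 1.74 MHz), repeated at `rep_rate_hz`
#' (default 2 kHz), digitized at `sample_rate_hz` (default 80 MHz).
#'
#' @param carrier_hz Carrier frequency, Hz.
#' @param n_cycles Number of carrier cycles per burst.
#' @param rep_rate_hz Burst repetition rate, Hz.
#' @param sample_rate_hz Digitizer sample rate, Hz (must exceed twice the
#'   carrier).
#' @param duration_us Rendered trace duration, microseconds; must cover the
#'   largest configured round trip plus the 45 us analysis window.
#' @return An object of class `burst_spec`.
#' @export
burst_spec <- function(carrier_hz = 1.74e6, n_cycles = 7, rep_rate_hz = 2e3,
                       sample_rate_hz = 80e6, duration_us = 300) {
  stopifnot(carrier_hz > 0, n_cycles >= 1, rep_rate_hz > 0, duration_us > 0)
  if (sample_rate_hz <= 2 * carrier_hz)
    stop("config error: sample rate must exceed twice the carrier frequency")
  structure(list(carrier_hz = carrier_hz, n_cycles = n_cycles,
                 rep_rate_hz = rep_rate_hz, sample_rate_hz = sample_rate_hz,
                 duration_us = duration_us), class = "burst_spec")
}

#' Synthesize one tone burst
#'
#' @param spec A [burst_spec()].
#' @return Numeric vector of `n_cycles / carrier` seconds of unit-amplitude
#'   sinusoid sampled at the spec rate.
#' @export
synth_burst <- function(spec) {
  stopifnot(inherits(spec, "burst_spec"))
  dur <- spec$n_cycles / spec$carrier_hz
  n <- ceiling(dur * spec$sample_rate_hz - 1e-9)
  sin(2 * pi * spec$carrier_hz * (0:(n - 1)) / spec$sample_rate_hz)
}

#' Measurement-noise specification
#'
#' Per-sample additive Gaussian noise, session-level multiplicative gain and
#' timing jitter (day-to-day environmental fluctuation), and
#' placement-level jitter: the transmitter is physically re-stepped to each
#' arc position for every pose and session, so each (pose, session,
#' transmitter) visit carries its own gain (aiming) and timing (positioning)
#' perturbation. A small aiming error moves the operating point on the steep
#' cosine directivity curve and so perturbs amplitude strongly, while the
#' specular path length — set by the transducer position, not its aim — is
#' unchanged to first order; hence the gain term is large relative to the
#' timing term. The placement terms reproduce the per-receiver spread of the
#' measured time-of-flight and amplitude distributions; without them the
#' Monte-Carlo arrival set would repeat exactly across sessions and
#' amplitude would become an unrealistically clean pose fingerprint.
#' When `additive_std` is `NULL` the dataset generator calibrates it so the
#' median noiseless single-trace peak sits `snr_db` above the noise floor
#' (default 6 dB: raw traces too noisy for direct peak picking, clean after
#' 10x averaging and filtering).
#'
#' @param additive_std Per-sample noise standard deviation (trace amplitude
#'   units), or `NULL` to calibrate from `snr_db`.
#' @param snr_db Target single-trace peak SNR used for calibration.
#' @param gain_jitter_sd Session gain jitter standard deviation
#'   (multiplicative, 1 = none).
#' @param timing_jitter_us Session timing jitter standard deviation,
#'   microseconds.
#' @param placement_gain_jitter_sd Log-normal sd of the per-placement gain.
#' @param placement_timing_jitter_us Per-placement timing jitter sd, us.
#' @param burst_gain_jitter_sd Per-burst multiplicative amplitude
#'   scintillation sd (drive and air-path fluctuation between bursts);
#'   averages down by sqrt(group size) in the grouped traces.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(additive_std = NULL, snr_db = 6, gain_jitter_sd = 0.05,
                       timing_jitter_us = 0.2,
                       placement_gain_jitter_sd = 0.25,
                       placement_timing_jitter_us = 0.1,
                       burst_gain_jitter_sd = 0.1) {
  stopifnot(is.null(additive_std) || additive_std >= 0, gain_jitter_sd >= 0,
            timing_jitter_us >= 0, placement_gain_jitter_sd >= 0,
            placement_timing_jitter_us >= 0, burst_gain_jitter_sd >= 0)
  structure(list(additive_std = additive_std, snr_db = snr_db,
                 gain_jitter_sd = gain_jitter_sd,
                 timing_jitter_us = timing_jitter_us,
                 placement_gain_jitter_sd = placement_gain_jitter_sd,
                 placement_timing_jitter_us = placement_timing_jitter_us,
                 burst_gain_jitter_sd = burst_gain_jitter_sd),
            class = "noise_spec")
}

#' Gaze-protocol specification
#'
#' The acquisition protocol of the gaze bench: a grid of goniometer poses, a
#' transmitter stepped over an arc opposite a fixed receiver, repeated bursts
#' per position, and multiple sessions. Defaults follow the study protocol:
#' 36 poses within +/-5 degrees, transmitter positions -90..90 in 10-degree
#' steps, 50 repeats, 9 sessions, receiver fixed at 180 degrees; consecutive
#' groups of 10 repeats are averaged downstream, so each pose yields
#' `sessions * repeats / group_size` (default 45) feature vectors.
#'
#' @param gaze_grid Two-column matrix or data.frame of (theta, phi) poses,
#'   degrees. Default: the 6 x 6 grid over {-5, -3, -1, 1, 3, 5}.
#' @param tx_positions_deg Transmitter arc positions, degrees.
#' @param repeats Bursts recorded per transmitter position.
#' @param sessions Number of recording sessions.
#' @param receiver_angle_deg Fixed receiver position on the ring.
#' @param group_size Traces averaged per feature vector (must divide
#'   `repeats`).
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(gaze_grid = NULL,
                          tx_positions_deg = seq(-90, 90, by = 10),
                          repeats = 50, sessions = 9,
                          receiver_angle_deg = 180, group_size = 10) {
  if (is.null(gaze_grid)) {
    g <- c(-5, -3, -1, 1, 3, 5)
    gaze_grid <- as.matrix(expand.grid(theta_deg = g, phi_deg = g))
  }
  gaze_grid <- as.matrix(gaze_grid)
  stopifnot(ncol(gaze_grid) == 2, repeats >= 1, sessions >= 1, group_size >= 1)
  if (repeats %% group_size != 0)
    stop("repeats (", repeats, ") not divisible by group size (", group_size,
         "): remainder ", repeats %% group_size)
  colnames(gaze_grid) <- c("theta_deg", "phi_deg")
  structure(list(gaze_grid = gaze_grid, tx_positions_deg = tx_positions_deg,
                 repeats = repeats, sessions = sessions,
                 receiver_angle_deg = receiver_angle_deg,
                 group_size = group_size), class = "protocol_spec")
}

#' Protocol bookkeeping
#'
#' @param protocol A [protocol_spec()].
#' @return data.frame of protocol counts: poses, transmitter positions,
#'   repeats, sessions, raw traces, feature vectors per pose, total feature
#'   vectors, and the effective post-averaging acquisition rate in Hz.
#' @export
protocol_manifest <- function(protocol) {
  stopifnot(inherits(protocol, "protocol_spec"))
  np <- nrow(protocol$gaze_grid)
  nt <- length(protocol$tx_positions_deg)
  fpp <- protocol$sessions * protocol$repeats / protocol$group_size
  data.frame(
    quantity = c("poses", "tx_positions", "repeats", "sessions", "raw_traces",
                 "features_per_pose", "feature_rows", "effective_rate_hz"),
    value = c(np, nt, protocol$repeats, protocol$sessions,
              np * nt * protocol$repeats * protocol$sessions, fpp, np * fpp,
              NA))
}

#' Effective acquisition rate after group averaging
#'
#' Averaging `group_size` consecutive bursts fired at the repetition rate
#' reduces the feature rate from the burst rate to
#' `rep_rate / group_size` (2 kHz / 10 = 200 Hz for the defaults).
#'
#' @param burst A [burst_spec()].
#' @param group_size Traces per average.
#' @return Rate in Hz.
#' @export
effective_rate_hz <- function(burst, group_size = 10) {
  stopifnot(inherits(burst, "burst_spec"), group_size >= 1)
  burst$rep_rate_hz / group_size
}

.render_cache <- new.env(parent = emptyenv())

#' Render a digitized receiver trace from arrival records
#'
#' The trace is the superposition, over arrivals, of the tone burst delayed
#' by the arrival time (plus any timing offset) and scaled by the arrival
#' weight, multiplied by the session gain, plus additive Gaussian noise drawn
#' from the current RNG state.
#'
#' @param arrivals data.frame from [trace_rays()] (any receiver mix; all rows
#'   are rendered).
#' @param burst A [burst_spec()].
#' @param noise_std Additive per-sample noise standard deviation.
#' @param gain Multiplicative session gain applied to the signal part.
#' @param timing_offset_us Session timing offset added to every arrival, us.
#' @return Numeric vector of `duration_us * sample_rate` samples.
#' @export
render_trace <- function(arrivals, burst, noise_std = 0, gain = 1,
                         timing_offset_us = 0) {
  stopifnot(inherits(burst, "burst_spec"))
  fs <- burst$sample_rate_hz
  n <- round(burst$duration_us * 1e-6 * fs)
  wave <- synth_burst(burst)
  x <- numeric(n)
  if (nrow(arrivals)) {
    t_us <- arrivals$time_us + timing_offset_us
    late <- t_us * 1e-6 * fs + length(wave) > n
    if (any(late))
      stop("config error: arrival at ", max(t_us[late]),
           " us exceeds the trace duration of ", burst$duration_us, " us")
    i0 <- round(t_us * 1e-6 * fs)
    if (nrow(arrivals) <= 32) {
      for (j in seq_len(nrow(arrivals))) {
        idx <- (i0[j] + 1):(i0[j] + length(wave))
        x[idx] <- x[idx] + arrivals$weight[j] * wave
      }
    } else {
      # impulse train convolved with the burst (FFT at a power-of-two
      # length, burst spectrum cached), cost independent of arrival count
      nfft <- 2^ceiling(log2(n + length(wave) - 1))
      key <- paste(burst$carrier_hz, burst$n_cycles, fs, nfft, sep = "|")
      if (is.null(.render_cache[[key]]))
        .render_cache[[key]] <- stats::fft(c(wave, numeric(nfft - length(wave))))
      imp <- numeric(nfft)
      agg <- rowsum(arrivals$weight, i0)
      imp[as.integer(rownames(agg)) + 1L] <- agg
      x <- Re(stats::fft(stats::fft(imp) * .render_cache[[key]],
                         inverse = TRUE))[seq_len(n)] / nfft
    }
  }
  x <- gain * x
  if (noise_std > 0) x <- x + stats::rnorm(n, 0, noise_std)
  x
}

# Arrival cache for one protocol: directional cone-sampled Monte-Carlo trace
# for every (pose, transmitter), receiver fixed. Returns a list indexed
# [[pose]][[tx]] of arrival data.frames.
protocol_arrivals <- function(protocol, eye_fun, occluder, ring, n_rays, seed,
                              max_bounces = 3, reflectance = c(occluder = 0.005)) {
  rx <- ring_transducer(ring, protocol$receiver_angle_deg, "receive")
  np <- nrow(protocol$gaze_grid)
  lapply(seq_len(np), function(p) {
    eye <- eye_fun(protocol$gaze_grid[p, ])
    scene <- make_scene(eye, occluder)
    lapply(seq_along(protocol$tx_positions_deg), function(ti) {
      tx <- ring_transducer(ring, protocol$tx_positions_deg[ti], "transmit")
      rays <- emit_rays(n_rays, "directional", tx,
                        seed = seed + 1009L * p + ti, sampling = "cone")
      trace_rays(rays, scene, list(rx = rx), max_bounces = max_bounces,
                 reflectance = reflectance)
    })
  })
}

#' Emulate the gaze-protocol bench and extract features
#'
#' Runs the full synthetic acquisition: one Monte-Carlo ray trace per
#' (pose, transmitter) — reused across repeats and sessions — then renders
#' digitized traces with per-session gain and timing jitter and per-sample
#' noise, applies the feature pipeline (group averaging, band-pass,
#' windowed peak detection) and assembles the long feature table. In
#' `"fast"` mode the group-averaged traces are synthesized directly
#' (statistically equivalent: the average of `group_size` i.i.d. renders is
#' the noiseless signal plus Gaussian noise at `std / sqrt(group_size)`);
#' `"full"` mode renders every repeat and averages explicitly. Counting and
#' feature outputs are invariant to the mode.
#'
#' @param protocol A [protocol_spec()].
#' @param occluder An [occluder_model()] or `NULL` (open-eye control).
#' @param ring A [transducer_ring()] containing the transmitter arc and the
#'   receiver position; default builds the standard bench ring.
#' @param burst A [burst_spec()].
#' @param noise A [noise_spec()].
#' @param n_rays Monte-Carlo rays per (pose, transmitter).
#' @param seed Integer seed; the dataset is bitwise reproducible given it.
#' @param mode `"fast"` or `"full"`.
#' @param eye_fun Function mapping a gaze pose `c(theta, phi)` to an
#'   [eye_model()]; default the standard bench eye.
#' @param max_bounces,reflectance Passed to the tracer.
#' @param filter_band,filter_order,window_us Feature-pipeline parameters
#'   (band-pass edges in Hz, Butterworth order, peak window width in us).
#' @return List: `features` (long data.frame: theta_deg, phi_deg, session, k,
#'   tx_deg, tof_us, amp), `manifest`, `noise_std` (the calibrated additive
#'   std), `protocol`, and the seed.
#' @export
simulate_bench_dataset <- function(protocol = protocol_spec(),
                                   occluder = occluder_model(),
                                   ring = NULL,
                                   burst = burst_spec(),
                                   noise = noise_spec(),
                                   n_rays = 131072, seed = 1,
                                   mode = c("fast", "full"),
                                   eye_fun = function(gaze) eye_model(gaze = gaze),
                                   max_bounces = 3,
                                   reflectance = c(occluder = 0.005),
                                   filter_band = c(1.6e6, 1.9e6),
                                   filter_order = 4, window_us = 45) {
  mode <- match.arg(mode)
  stopifnot(inherits(protocol, "protocol_spec"), inherits(burst, "burst_spec"),
            inherits(noise, "noise_spec"))
  if (is.null(ring)) {
    angles <- unique(c(protocol$tx_positions_deg, protocol$receiver_angle_deg))
    ring <- transducer_ring(angles, ring_radius = 15, standoff = 25,
                            aperture_radius = 2)
  }
  arr <- protocol_arrivals(protocol, eye_fun, occluder, ring, n_rays, seed,
                           max_bounces, reflectance)

  # calibrate the additive noise std against the noiseless single-trace peaks
  noise_std <- noise$additive_std
  if (is.null(noise_std)) {
    peaks <- unlist(lapply(arr, function(per_pose)
      vapply(per_pose, function(a)
        if (nrow(a)) max(abs(render_trace(a, burst))) else NA_real_,
        numeric(1))))
    med <- stats::median(peaks, na.rm = TRUE)
    if (!is.finite(med) || med == 0)
      stop("cannot calibrate noise: no detected arrivals anywhere")
    noise_std <- med / 10^(noise$snr_db / 20)
  }

  np <- nrow(protocol$gaze_grid)
  nt <- length(protocol$tx_positions_deg)
  ngroups <- protocol$repeats / protocol$group_size
  fs <- burst$sample_rate_hz

  rows <- with_local_seed(seed, {
    gains <- 1 + stats::rnorm(protocol$sessions, 0, noise$gain_jitter_sd)
    dts <- stats::rnorm(protocol$sessions, 0, noise$timing_jitter_us)
    sg <- noise$placement_gain_jitter_sd
    pl_gain <- array(exp(stats::rnorm(np * protocol$sessions * nt,
                                      -sg^2 / 2, sg)),
                     dim = c(np, protocol$sessions, nt))
    pl_dt <- array(stats::rnorm(np * protocol$sessions * nt, 0,
                                noise$placement_timing_jitter_us),
                   dim = c(np, protocol$sessions, nt))
    out <- vector("list", np * nt * protocol$sessions * ngroups)
    i <- 0L
    for (p in seq_len(np)) for (s in seq_len(protocol$sessions)) {
      for (ti in seq_len(nt)) {
        a <- arr[[p]][[ti]]
        g_eff <- gains[s] * pl_gain[p, s, ti]
        dt_eff <- dts[s] + pl_dt[p, s, ti]
        sb <- noise$burst_gain_jitter_sd
        if (mode == "fast") {
          # a group average of group_size i.i.d. per-burst gains
          gk <- g_eff * (1 + stats::rnorm(ngroups, 0,
                                          sb / sqrt(protocol$group_size)))
          avg <- vapply(seq_len(ngroups), function(k)
            render_trace(a, burst,
                         noise_std = noise_std / sqrt(protocol$group_size),
                         gain = gk[k], timing_offset_us = dt_eff),
            numeric(round(burst$duration_us * 1e-6 * fs)))
        } else {
          gj <- g_eff * (1 + stats::rnorm(protocol$repeats, 0, sb))
          raw <- vapply(seq_len(protocol$repeats), function(j)
            render_trace(a, burst, noise_std = noise_std, gain = gj[j],
                         timing_offset_us = dt_eff),
            numeric(round(burst$duration_us * 1e-6 * fs)))
          avg <- average_groups(raw, protocol$group_size)
        }
        for (k in seq_len(ngroups)) {
          f <- bandpass(avg[, k], fs, filter_band[1], filter_band[2],
                        filter_order)
          pk <- extract_peak_features(avg[, k], f, fs, window_us)
          i <- i + 1L
          out[[i]] <- c(protocol$gaze_grid[p, 1], protocol$gaze_grid[p, 2],
                        s - 1, k - 1, protocol$tx_positions_deg[ti],
                        pk[["tof_us"]], pk[["amp"]])
        }
      }
    }
    out
  })
  feats <- as.data.frame(do.call(rbind, rows))
  names(feats) <- c("theta_deg", "phi_deg", "session", "k", "tx_deg",
                    "tof_us", "amp")
  man <- protocol_manifest(protocol)
  man$value[man$quantity == "effective_rate_hz"] <-
    effective_rate_hz(burst, protocol$group_size)
  list(features = feats, manifest = man, noise_std = noise_std,
       protocol = protocol, seed = seed)
}

#' Attenuation sweep (flat-plate test bench)
#'
#' A transducer pair faces a flat plate on a translation stage; for each
#' plate distance the axial specular echo (round trip `2 d`) is traced,
#' rendered and peak-picked. Peak amplitude decays as `10^(-2 A d / 20)`.
#'
#' @param distances_mm Plate distances (> 0), mm.
#' @param burst A [burst_spec()]; duration is extended automatically to
#'   cover the longest round trip.
#' @param db_per_m Absorption attenuation coefficient.
#' @return data.frame `distance_mm`, `peak_amplitude`, `round_trip_us`.
#' @export
bench1_attenuation_sweep <- function(distances_mm, burst = burst_spec(),
                                     db_per_m = ATTENUATION_AIR) {
  stopifnot(all(distances_mm > 0))
  t_max <- 2 * max(distances_mm) / 0.343 # us
  if (burst$duration_us < t_max + 10)
    burst <- burst_spec(burst$carrier_hz, burst$n_cycles, burst$rep_rate_hz,
                        burst$sample_rate_hz, duration_us = t_max + 10)
  res <- lapply(distances_mm, function(d) {
    tx <- transducer(c(0, 0, 0), c(0, 0, 1), "transmit")
    rx <- transducer(c(0, 0, 0), c(0, 0, 1), "receive", aperture_radius = 1)
    rays <- directed_rays(tx, c(0, 0, 1))
    a <- trace_rays(rays, plate_scene(d), list(rx = rx),
                    attenuation_db_per_m = db_per_m)
    x <- render_trace(a, burst)
    data.frame(distance_mm = d, peak_amplitude = max(x),
               round_trip_us = if (nrow(a)) a$time_us[1] else NA_real_)
  })
  do.call(rbind, res)
}

#' Directivity sweep (rotating-transmitter test bench)
#'
#' A facing transducer pair at a fixed separation; the transmitter is
#' rotated in steps and the received peak amplitude recorded. The received
#' amplitude follows the directivity weight `w(alpha)` times the fixed
#' facing-pair attenuation factor, and is zero at and beyond the cutoff.
#'
#' @param angles_deg Transmitter rotation angles, degrees.
#' @param separation_mm Pair separation, mm.
#' @param cutoff_deg Directivity half-angle cutoff.
#' @param burst A [burst_spec()].
#' @return data.frame `angle_deg`, `amplitude`.
#' @export
bench2_directivity_sweep <- function(angles_deg, separation_mm = 50,
                                     cutoff_deg = 15, burst = burst_spec()) {
  res <- lapply(angles_deg, function(a) {
    # rotating the transmitter by `a` puts the receiver at angle |a| off the
    # transmit axis; the receiver still faces the transmitter (alpha_rx = 0)
    tx <- transducer(c(0, 0, 0), c(sin(a * DEG), 0, cos(a * DEG)), "transmit",
                     acceptance_half_angle = cutoff_deg)
    rx <- transducer(c(0, 0, separation_mm), c(0, 0, -1), "receive",
                     acceptance_half_angle = cutoff_deg)
    rays <- directed_rays(tx, c(0, 0, 1)) # ray toward the receiver
    w <- rays$weight[1]
    amp <- if (abs(a) >= cutoff_deg) 0 else
      w * attenuation_factor(separation_mm)
    if (amp > 0) {
      arr <- data.frame(receiver_id = "rx", path_mm = separation_mm,
                        time_us = separation_mm / 0.343, n_bounces = 0L,
                        weight = amp)
      b2 <- burst
      if (b2$duration_us < separation_mm / 0.343 + 10)
        b2 <- burst_spec(b2$carrier_hz, b2$n_cycles, b2$rep_rate_hz,
                         b2$sample_rate_hz,
                         duration_us = separation_mm / 0.343 + 10)
      amp <- max(render_trace(arr, b2))
    }
    data.frame(angle_deg = a, amplitude = amp)
  })
  do.call(rbind, res)
}
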