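# Configuration and dataset I/O: structured YAML run configuration with
# strict key checking, config hashing for provenance, and CSV writers with
# JSON metadata sidecars.

default_run_config <- function() {
  list(
    geometry = list(
      sclera_radius_mm = 11.925, cornea_radius_mm = 7.8,
      cornea_offset_mm = 5.6,
      occluder = list(enabled = TRUE, aperture_halfwidth_mm = 3.2,
                      aperture_halfheight_mm = 3.2,
                      aperture_center_mm = c(0, -0.3), standoff_mm = 14.3,
                      wedge_angle_deg = c(110, -120),
                      wedge_extent_deg = c(140, 120),
                      wedge_protrusion_mm = c(2.9, 2.3),
                      wedge_softness_mm = c(2.8, 2.0),
                      edge_softness_mm = 1.0),
      ring = list(ring_radius_mm = 15, standoff_mm = 25,
                  aperture_radius_mm = 2, acceptance_half_angle_deg = 15)),
    protocol = list(gaze_values_deg = c(-5, -3, -1, 1, 3, 5),
                    tx_min_deg = -90, tx_max_deg = 90, tx_step_deg = 10,
                    repeats = 50, sessions = 9, receiver_angle_deg = 180,
                    group_size = 10),
    burst = list(carrier_hz = 1.74e6, n_cycles = 7, rep_rate_hz = 2000,
                 sample_rate_hz = 80e6, duration_us = 300),
    noise = list(additive_std = NULL, snr_db = 6, gain_jitter_sd = 0.05,
                 timing_jitter_us = 0.2, placement_gain_jitter_sd = 0.25,
                 placement_timing_jitter_us = 0.1, burst_gain_jitter_sd = 0.1),
    simulation = list(n_rays = 131072, max_bounces = 3,
                      occluder_reflectance = 0.005, mode = "fast"),
    features = list(band_low_hz = 1.6e6, band_high_hz = 1.9e6,
                    filter_order = 4, window_us = 45),
    regression = list(learning_rate = 0.0825, max_depth = 5, n_trees = 750,
                      min_child_weight = 23, alpha_reg = 0.01,
                      lambda_reg = 1, folds = 5),
    seed = 1)
}

check_known_keys <- function(cfg, ref, path = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown))
    stop("unknown config key(s): ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(cfg))
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]])) && is.list(cfg[[k]]))
      check_known_keys(cfg[[k]], ref[[k]], paste0(path, k, "."))
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && !is.null(names(base[[k]])) &&
        is.list(override[[k]]))
      base[[k]] <- merge_config(base[[k]], override[[k]])
    else base[[k]] <- override[[k]]
  }
  base
}

#' Read a run configuration
#'
#' Loads a YAML run configuration, fills unspecified values from the
#' defaults, and rejects unknown keys. Units in the file are mm, degrees,
#' Hz and microseconds.
#'
#' @param path YAML file path, or `NULL` for the full default configuration.
#' @return A named configuration list (class `run_config`).
#' @export
read_run_config <- function(path = NULL) {
  ref <- default_run_config()
  cfg <- if (is.null(path)) ref else {
    user <- yaml::read_yaml(path)
    check_known_keys(user, ref)
    merge_config(ref, user)
  }
  structure(cfg, class = "run_config")
}

#' Hash of a configuration (or any serializable object)
#'
#' MD5 of the canonical JSON encoding; recorded in output sidecars so every
#' artifact is traceable to the configuration and seed that produced it.
#'
#' @param x Object to hash.
#' @return Hex string.
#' @export
config_hash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                              null = "null", force = TRUE), tf)
  unname(tools::md5sum(tf))
}

# Build the constructor arguments for a run_config
config_objects <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  g <- cfg$geometry
  occ <- if (isTRUE(g$occluder$enabled))
    occluder_model(g$occluder$aperture_halfwidth_mm,
                   g$occluder$aperture_halfheight_mm,
                   g$occluder$aperture_center_mm, g$occluder$standoff_mm,
                   g$occluder$wedge_angle_deg, g$occluder$wedge_extent_deg,
                   g$occluder$wedge_protrusion_mm,
                   g$occluder$wedge_softness_mm,
                   g$occluder$edge_softness_mm) else NULL
  pr <- cfg$protocol
  protocol <- protocol_spec(
    gaze_grid = as.matrix(expand.grid(theta_deg = pr$gaze_values_deg,
                                      phi_deg = pr$gaze_values_deg)),
    tx_positions_deg = seq(pr$tx_min_deg, pr$tx_max_deg, by = pr$tx_step_deg),
    repeats = pr$repeats, sessions = pr$sessions,
    receiver_angle_deg = pr$receiver_angle_deg, group_size = pr$group_size)
  ring <- transducer_ring(
    unique(c(protocol$tx_positions_deg, protocol$receiver_angle_deg)),
    ring_radius = g$ring$ring_radius_mm, standoff = g$ring$standoff_mm,
    apex_z = g$cornea_offset_mm + g$cornea_radius_mm,
    aperture_radius = g$ring$aperture_radius_mm,
    acceptance_half_angle = g$ring$acceptance_half_angle_deg)
  list(
    protocol = protocol, ring = ring, occluder = occ,
    eye_fun = function(gaze) eye_model(g$sclera_radius_mm, g$cornea_radius_mm,
                                       g$cornea_offset_mm, gaze),
    burst = do.call(burst_spec, cfg$burst),
    noise = do.call(noise_spec, cfg$noise),
    gbrt = gbrt_config(cfg$regression$learning_rate, cfg$regression$max_depth,
                       cfg$regression$n_trees, cfg$regression$min_child_weight,
                       cfg$regression$alpha_reg, cfg$regression$lambda_reg))
}

#' Run the bench emulation from a configuration
#'
#' Convenience wrapper: builds all simulation objects from a [read_run_config()]
#' configuration and calls [simulate_bench_dataset()].
#'
#' @param cfg A `run_config`.
#' @param seed Overrides `cfg$seed` when given.
#' @param n_rays Overrides `cfg$simulation$n_rays` when given.
#' @return As [simulate_bench_dataset()], plus `config_hash`.
#' @export
run_bench_from_config <- function(cfg = read_run_config(), seed = NULL,
                                  n_rays = NULL) {
  ob <- config_objects(cfg)
  ds <- simulate_bench_dataset(
    protocol = ob$protocol, occluder = ob$occluder, ring = ob$ring,
    burst = ob$burst, noise = ob$noise,
    n_rays = if (is.null(n_rays)) cfg$simulation$n_rays else n_rays,
    seed = if (is.null(seed)) cfg$seed else seed,
    mode = cfg$simulation$mode, eye_fun = ob$eye_fun,
    max_bounces = cfg$simulation$max_bounces,
    reflectance = c(occluder = cfg$simulation$occluder_reflectance),
    filter_band = c(cfg$features$band_low_hz, cfg$features$band_high_hz),
    filter_order = cfg$features$filter_order,
    window_us = cfg$features$window_us)
  ds$config_hash <- config_hash(unclass(cfg))
  ds
}

#' Write a table as CSV with a JSON metadata sidecar
#'
#' @param df data.frame to write.
#' @param path CSV path; the sidecar is written next to it as
#'   `<path>.meta.json`.
#' @param meta Named list of provenance fields (seed, config hash, counts...).
#' @return `path`, invisibly.
#' @export
write_csv_with_sidecar <- function(df, path, meta = list()) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  meta$rows <- nrow(df)
  meta$columns <- names(df)
  meta$written <- format(Sys.time(), tz = "UTC", usetz = TRUE)
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
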