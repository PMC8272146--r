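# Acoustic physics and Monte-Carlo ray tracing: impedance-mismatch
# reflection, air attenuation, cosine-type transducer directivity, seeded
# hemisphere emission, and propagation to directional disc receivers.

SOUND_SPEED_AIR <- 343      # m/s
ATTENUATION_AIR <- 470      # dB/m at ~1.7 MHz

#' Acoustic medium
#'
#' @param density kg/m^3.
#' @param speed Sound speed, m/s.
#' @return List with density, speed and impedance `Z = density * speed`
#'   (kg/(m^2 s)).
#' @export
medium_properties <- function(density, speed) {
  stopifnot(density > 0, speed > 0)
  list(density = density, speed = speed, Z = density * speed)
}

#' Fraction of incident sound energy reflected at a planar interface
#'
#' `R = ((Z2 - Z1) / (Z2 + Z1))^2`. The air-tissue and air-glass mismatches
#' make solid surfaces nearly perfect acoustic mirrors (> 99.8% reflected),
#' which motivates the tracer's default of total reflection.
#'
#' @param medium1,medium2 [medium_properties()] objects.
#' @return Dimensionless fraction in `[0, 1]`, symmetric in its arguments.
#' @export
reflection_fraction <- function(medium1, medium2) {
  z1 <- medium1$Z
  z2 <- medium2$Z
  if (z1 <= 0 || z2 <= 0) stop("impedances must be positive")
  ((z2 - z1) / (z2 + z1))^2
}

#' Transducer directivity weight
#'
#' `w(alpha) = cos(min(alpha * 90 / cutoff, 90 degrees))`: 1 on axis, zero at
#' and beyond the cutoff (default 15 degrees), monotone in between. The same
#' curve applies in transmit and receive mode.
#'
#' @param alpha_deg Angle between the ray and the transducer axis, degrees
#'   (vectorized, must be non-negative).
#' @param cutoff_deg Half-angle cutoff, degrees.
#' @return Weight(s) in `[0, 1]`.
#' @export
directional_weight <- function(alpha_deg, cutoff_deg = 15) {
  if (any(alpha_deg < 0)) stop("alpha must be non-negative")
  w <- cos(pmin(alpha_deg * (90 / cutoff_deg), 90) * DEG)
  w[alpha_deg >= cutoff_deg] <- 0 # exact zero at and beyond the cutoff
  w
}

#' Amplitude attenuation over a path in air
#'
#' `10^(-A d / 20)` with the absorption coefficient `A` in dB/m (default 470,
#' appropriate for ~1.7 MHz airborne ultrasound) and `d` in mm.
#'
#' @param d_mm Path length, mm (vectorized, non-negative).
#' @param db_per_m Absorption attenuation coefficient, dB/m.
#' @return Amplitude factor(s) in `(0, 1]`; 1 at zero distance.
#' @export
attenuation_factor <- function(d_mm, db_per_m = ATTENUATION_AIR) {
  if (any(d_mm < 0)) stop("distance must be non-negative")
  10^(-db_per_m * (d_mm / 1000) / 20)
}

# Evaluate an expression with a private RNG state so that package-level
# simulation is deterministic given its own seed and leaves the caller's
# stream untouched.
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Orthonormal basis (u, v) perpendicular to unit vector w.
perp_basis <- function(w) {
  a <- if (abs(w[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unitize(pracma_cross(a, w))
  v <- pracma_cross(w, u)
  list(u = u, v = v)
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Emit rays from a transducer
#'
#' Samples `n` ray directions uniformly (per solid angle) on the emission
#' hemisphere around the transducer axis, deterministically for a given seed.
#' In `"directional"` mode each ray carries the emission directivity weight
#' `w(alpha)`; in `"omnidirectional"` mode all weights are 1.
#'
#' With `sampling = "cone"` directions are drawn uniformly from the spherical
#' cap inside the directivity cutoff only, and weights are multiplied by the
#' cap/hemisphere solid-angle ratio. Because rays outside the cutoff carry
#' exactly zero weight, this is an importance-sampling scheme with the same
#' expectation as hemisphere sampling at a much lower variance; it is what
#' the bench emulator uses.
#'
#' @param n Number of rays.
#' @param mode `"directional"` or `"omnidirectional"`.
#' @param tx A [transducer()].
#' @param seed Integer seed.
#' @param sampling `"hemisphere"` (default) or `"cone"` (directional only).
#' @return List with `origin` (n x 3), `direction` (n x 3), `weight` (n),
#'   `mode`, and the transducer.
#' @export
emit_rays <- function(n, mode = c("directional", "omnidirectional"), tx, seed,
                      sampling = c("hemisphere", "cone")) {
  mode <- match.arg(mode)
  sampling <- match.arg(sampling)
  stopifnot(n >= 1, inherits(tx, "transducer"))
  if (sampling == "cone" && mode != "directional")
    stop("cone sampling only applies to directional emission")
  cutoff <- tx$acceptance_half_angle
  cos_min <- if (sampling == "cone") cos(cutoff * DEG) else 0
  dirs <- with_local_seed(seed, {
    cz <- runif(n, cos_min, 1)            # uniform per solid angle
    az <- runif(n, 0, 2 * pi)
    cbind(cz, sqrt(pmax(0, 1 - cz^2)) * cos(az),
          sqrt(pmax(0, 1 - cz^2)) * sin(az))
  })
  b <- perp_basis(tx$direction)
  D <- dirs[, 1] %o% tx$direction + dirs[, 2] %o% b$u + dirs[, 3] %o% b$v
  alpha <- acos(pmin(1, pmax(-1, dirs[, 1]))) / DEG
  w <- if (mode == "directional") directional_weight(alpha, cutoff) else
    rep(1, n)
  if (sampling == "cone") w <- w * (1 - cos_min) # cap / hemisphere ratio
  list(origin = matrix(tx$position, n, 3, byrow = TRUE), direction = D,
       weight = w, mode = mode, transducer = tx)
}

#' Build a ray set from explicit directions
#'
#' Deterministic counterpart of [emit_rays()]: rays leave the transducer
#' position along the given directions. Emission weights default to the
#' directivity weight of each direction against the transducer axis.
#'
#' @param tx A [transducer()].
#' @param directions n x 3 matrix (rows normalized internally).
#' @param weights Optional explicit emission weights.
#' @return A ray set as from [emit_rays()].
#' @export
directed_rays <- function(tx, directions, weights = NULL) {
  stopifnot(inherits(tx, "transducer"))
  if (is.null(dim(directions))) directions <- matrix(directions, 1)
  D <- directions / sqrt(rowSums(directions^2))
  alpha <- acos(pmin(1, pmax(-1, as.vector(D %*% tx$direction)))) / DEG
  if (is.null(weights))
    weights <- directional_weight(alpha, tx$acceptance_half_angle)
  list(origin = matrix(tx$position, nrow(D), 3, byrow = TRUE), direction = D,
       weight = weights, mode = "directional", transducer = tx)
}

#' Trace rays through a scene to disc receivers
#'
#' Propagates each ray with specular reflections (reflectance treated as
#' total, justified by the > 99.8% air-solid reflection fraction; a lower
#' per-bounce reflectance can be configured) until it crosses a receiver's
#' aperture disc, exceeds `max_bounces` reflections, or escapes. A detected
#' ray yields one arrival record with
#' `weight = emission weight x w(arrival alpha) x attenuation(full path)`;
#' in directional mode rays arriving outside the acceptance cutoff are
#' rejected before they are counted. Detected rays are absorbed; rejected
#' rays pass through the disc.
#'
#' @param rays Output of [emit_rays()].
#' @param scene A [make_scene()] scene.
#' @param receivers List of receive-mode [transducer()]s (names become
#'   receiver ids).
#' @param max_bounces Maximum number of surface reflections (default 3).
#' @param mode Reception directivity: `"directional"` applies the weight and
#'   cutoff, `"omnidirectional"` accepts every crossing with weight 1.
#' @param reflectance Per-bounce specular amplitude reflectance: a scalar,
#'   or a named vector keyed by surface id (e.g.
#'   `c(sclera = 1, cornea = 1, occluder = 0.1)`); unnamed surfaces get 1.
#'   Values below 1 model energy lost to diffuse scattering at rough or
#'   compliant surfaces while keeping the occlusion (blocking) geometry
#'   exact.
#' @param attenuation_db_per_m,sound_speed_m_s Medium parameters.
#' @return data.frame with columns `receiver_id`, `path_mm`, `time_us`,
#'   `n_bounces`, `weight` (one row per detected ray; zero rows if none).
#' @export
trace_rays <- function(rays, scene, receivers, max_bounces = 3,
                       mode = c("directional", "omnidirectional"),
                       reflectance = 1,
                       attenuation_db_per_m = ATTENUATION_AIR,
                       sound_speed_m_s = SOUND_SPEED_AIR) {
  mode <- match.arg(mode)
  stopifnot(max_bounces >= 1, inherits(scene, "scene"), length(receivers) >= 1)
  if (is.null(names(receivers)))
    names(receivers) <- as.character(seq_along(receivers))
  n <- nrow(rays$origin)
  O <- rays$origin
  D <- rays$direction
  w_emit <- rays$weight
  path <- numeric(n)
  bounces <- integer(n)
  amp <- rep(1, n) # accumulated per-bounce reflectance
  active <- w_emit > 0
  out <- vector("list", max_bounces + 2)
  seg <- 0

  while (any(active) && seg <= max_bounces) {
    seg <- seg + 1
    idx <- which(active)
    Oi <- O[idx, , drop = FALSE]
    Di <- D[idx, , drop = FALSE]
    hit <- scene_intersect(Oi, Di, scene)
    t_surf <- hit$t

    # penumbral occluder crossing on this segment: the ray passes the shell
    # plane inside the soft shadow and its amplitude is scaled by the local
    # transmission (full shadow is a reflecting surface hit instead)
    t_soft <- rep(Inf, length(idx))
    T_soft <- rep(1, length(idx))
    occ <- scene$occluder
    if (!is.null(occ)) {
      dzc <- Di[, 3]
      tp <- ifelse(abs(dzc) > 0, (occ$standoff - Oi[, 3]) / dzc, Inf)
      tp[tp <= T_MIN] <- Inf
      cross <- is.finite(tp) & tp < t_surf
      if (any(cross)) {
        px <- Oi[cross, 1] + tp[cross] * Di[cross, 1]
        py <- Oi[cross, 2] + tp[cross] * Di[cross, 2]
        Tt <- aperture_transmission(occ, px, py)
        sub <- which(cross)[Tt < 1]
        t_soft[sub] <- tp[cross][Tt < 1]
        T_soft[sub] <- Tt[Tt < 1]
      }
    }

    # earliest accepted receiver crossing on this segment
    t_det <- rep(Inf, length(idx))
    det_rid <- rep(NA_character_, length(idx))
    det_w <- rep(NA_real_, length(idx))
    for (rid in names(receivers)) {
      rc <- receivers[[rid]]
      dn <- as.vector(Di %*% rc$direction)
      approaching <- dn < 0 # moving against the receiver's facing direction
      tr <- rep(Inf, length(idx))
      tr[approaching] <- as.vector(
        (sum(rc$position * rc$direction) -
           Oi[approaching, , drop = FALSE] %*% rc$direction) / dn[approaching])
      ok <- is.finite(tr) & tr > T_MIN & tr < t_surf
      if (!any(ok)) next
      P <- Oi[ok, , drop = FALSE] + tr[ok] * Di[ok, , drop = FALSE]
      r2 <- rowSums(sweep(P, 2, rc$position)^2)
      ok[ok] <- r2 <= rc$aperture_radius^2
      if (!any(ok)) next
      wr_full <- rep(NA_real_, length(idx))
      accept <- ok
      alpha <- acos(pmin(1, pmax(-1, -dn[ok]))) / DEG
      if (mode == "directional") {
        wr_full[ok] <- directional_weight(alpha, rc$acceptance_half_angle)
        accept[ok] <- alpha < rc$acceptance_half_angle
      } else {
        wr_full[ok] <- 1
      }
      better <- accept & tr < t_det
      t_det[better] <- tr[better]
      det_rid[better] <- rid
      det_w[better] <- wr_full[better]
    }

    detected <- is.finite(t_det)
    if (any(detected)) {
      gi <- idx[detected]
      plen <- path[gi] + t_det[detected]
      soft_fac <- ifelse(t_soft[detected] < t_det[detected],
                         T_soft[detected], 1)
      out[[seg]] <- data.frame(
        receiver_id = det_rid[detected],
        path_mm = plen,
        time_us = plen / (sound_speed_m_s * 1e3) * 1e6,
        n_bounces = bounces[gi],
        weight = w_emit[gi] * amp[gi] * soft_fac * det_w[detected] *
          attenuation_factor(plen, attenuation_db_per_m),
        stringsAsFactors = FALSE)
      active[gi] <- FALSE
    }

    # remaining rays: reflect at the surface hit (if any, and bounce budget)
    cont <- !detected & is.finite(t_surf)
    gi <- idx[cont]
    drop <- idx[!detected & !is.finite(t_surf)]
    active[drop] <- FALSE
    if (length(gi)) {
      over <- bounces[gi] + 1L > max_bounces
      ti <- t_surf[cont]
      path[gi] <- path[gi] + ti
      O[gi, ] <- hit$point[cont, , drop = FALSE]
      Nrm <- hit$normal[cont, , drop = FALSE]
      Dg <- D[gi, , drop = FALSE]
      D[gi, ] <- Dg - 2 * rowSums(Dg * Nrm) * Nrm
      bounces[gi] <- bounces[gi] + 1L
      refl <- if (is.null(names(reflectance))) rep(reflectance[1], length(gi))
        else {
          r <- reflectance[hit$surface[cont]]
          r[is.na(r)] <- 1
          unname(r)
        }
      amp[gi] <- amp[gi] * refl *
        ifelse(t_soft[cont] < t_surf[cont], T_soft[cont], 1)
      active[gi[over]] <- FALSE
    }
  }

  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(res))
    res <- data.frame(receiver_id = character(), path_mm = numeric(),
                      time_us = numeric(), n_bounces = integer(),
                      weight = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Weighted arrival-time histogram per receiver
#'
#' @param arrivals data.frame from [trace_rays()].
#' @param bin_us Time bin width, microseconds (> 0).
#' @param t_max_us Histogram upper edge; defaults to the latest arrival.
#' @return data.frame `receiver_id`, `bin_start_us`, `weight` (occupied bins
#'   only; zero rows for empty arrivals). Total histogram mass equals the
#'   total arrival weight.
#' @export
receiver_histogram <- function(arrivals, bin_us, t_max_us = NULL) {
  stopifnot(bin_us > 0)
  if (nrow(arrivals) == 0)
    return(data.frame(receiver_id = character(), bin_start_us = numeric(),
                      weight = numeric(), stringsAsFactors = FALSE))
  bin <- floor(arrivals$time_us / bin_us)
  agg <- stats::aggregate(weight ~ receiver_id + bin, data =
                            cbind(arrivals["weight"],
                                  receiver_id = arrivals$receiver_id,
                                  bin = bin), FUN = sum)
  data.frame(receiver_id = agg$receiver_id,
             bin_start_us = agg$bin * bin_us,
             weight = agg$weight, stringsAsFactors = FALSE)
}
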