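# Scene geometry: sphere-on-sphere model eye, parametric occluder, transducer
# ring, and analytic ray-surface intersection.
#
# Coordinate convention (used everywhere): right-handed, origin at the sclera
# center, +z toward the transducer ring, +x temporal -> nasal, +y up.
# Horizontal gaze theta rotates about +y (positive = nasal), vertical gaze phi
# about +x (positive = up); gaze (0, 0) points at the ring center. Units are
# mm and degrees throughout.

DEG <- pi / 180
# relative geometric tolerance; tangent hits resolve to "hit"
GEOM_RTOL <- 1e-9
# minimum ray parameter, guards against self-intersection after a bounce
T_MIN <- 1e-6

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n == 0) stop("cannot normalize a zero vector")
  v / n
}

#' Rotation matrix for a gaze pose
#'
#' Composes the vertical rotation (about +x) with the horizontal rotation
#' (about +y) so that the rest gaze axis +z maps to the posed gaze axis.
#'
#' @param theta_deg Horizontal gaze angle in degrees (positive toward +x).
#' @param phi_deg Vertical gaze angle in degrees (positive toward +y).
#' @return A 3x3 rotation matrix.
#' @export
gaze_rotation <- function(theta_deg, phi_deg) {
  th <- theta_deg * DEG
  ph <- -phi_deg * DEG # sign so that positive phi tilts the gaze axis up (+y)
  ry <- matrix(c(cos(th), 0, -sin(th), 0, 1, 0, sin(th), 0, cos(th)), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3, 3)
  ry %*% rx
}

#' Sphere-on-sphere model eye
#'
#' A scleral sphere with a smaller corneal sphere whose center is offset from
#' the sclera center along the gaze axis; the protruding corneal cap is what
#' makes echo timing gaze-dependent. Defaults are the bench dimensions:
#' cornea radius 7.8 mm, sclera radius 11.925 mm, offset 5.6 mm, so the
#' corneal apex protrudes 1.475 mm beyond the scleral surface.
#'
#' @param sclera_radius,cornea_radius,cornea_offset Geometry in mm.
#' @param gaze Numeric `c(theta, phi)` gaze pose in degrees.
#' @param sclera_center Sclera center (fixed by convention at the origin).
#' @return An object of class `eye_model`.
#' @export
eye_model <- function(sclera_radius = 11.925, cornea_radius = 7.8,
                      cornea_offset = 5.6, gaze = c(0, 0),
                      sclera_center = c(0, 0, 0)) {
  stopifnot(sclera_radius > 0, cornea_radius > 0, cornea_offset >= 0,
            length(gaze) == 2, length(sclera_center) == 3)
  if (cornea_offset + cornea_radius <= sclera_radius)
    stop("invalid geometry: cornea does not protrude beyond the sclera ",
         "(offset + cornea_radius <= sclera_radius)")
  rot <- gaze_rotation(gaze[1], gaze[2])
  axis <- as.vector(rot %*% c(0, 0, 1))
  structure(list(
    sclera_center = sclera_center,
    sclera_radius = sclera_radius,
    cornea_radius = cornea_radius,
    cornea_offset = cornea_offset,
    gaze = gaze,
    gaze_axis = axis,
    cornea_center = sclera_center + cornea_offset * axis
  ), class = "eye_model")
}

#' Corneal apex position of a posed eye
#'
#' @param eye An [eye_model()].
#' @return 3-vector, mm.
#' @export
corneal_apex <- function(eye) {
  eye$cornea_center + eye$cornea_radius * eye$gaze_axis
}

#' Parametric occluder shell
#'
#' A reflective shell in the plane z = `standoff` in front of the eye with an
#' elliptical aperture plus one or more wedges that narrow the aperture over
#' angular sectors. It is a parametric proxy for facial occlusions (lids,
#' brow, nose pad): rays through the aperture pass, all other rays reflect
#' off the shell. `aperture_center` shifts the aperture in the shell plane;
#' the default wedges are a broad upper shelf (upper lid / brow) and a
#' lower-temporal edge (lower lid / cheek / nose pad), which together
#' produce the occlusion signatures seen on a real face: amplitude
#' asymmetry across transmitter positions and degraded signal for downward
#' gaze (the lower-temporal edge progressively clips the reflected bundles
#' as the cornea rotates down).
#'
#' @param aperture_halfwidth,aperture_halfheight Aperture semi-axes, mm.
#' @param aperture_center Length-2 (x, y) aperture center in the shell plane, mm.
#' @param standoff Shell plane distance from the sclera center along +z, mm;
#'   must exceed the scleral radius so the shell is strictly outside the eye.
#' @param wedge_angle Angular positions of the wedges in the shell plane,
#'   degrees from +x (the nasal direction); vectors describe several wedges.
#' @param wedge_extent Full angular extent of each wedge, degrees.
#' @param wedge_protrusion Radial narrowing of the aperture inside each wedge
#'   sector, mm (overlapping sectors take the strongest cut).
#' @param wedge_softness Penumbra width of each wedge edge, mm: transmission
#'   ramps linearly from 1 at the (narrowed) edge to 0 at `softness` beyond
#'   it. At 1.7 MHz the acoustic wavelength is ~0.2 mm and edge diffraction
#'   smooths geometric shadows over roughly the Fresnel-zone width
#'   sqrt(lambda d) ~ 2 mm, so occlusion grades signal rather than
#'   switching it off.
#' @param edge_softness Penumbra width of the elliptical aperture edge, mm.
#' @return An object of class `occluder_model`.
#' @export
occluder_model <- function(aperture_halfwidth = 3.2, aperture_halfheight = 3.2,
                           aperture_center = c(0, -0.3), standoff = 14.3,
                           wedge_angle = c(110, -120),
                           wedge_extent = c(140, 120),
                           wedge_protrusion = c(2.9, 2.3),
                           wedge_softness = c(2.8, 2.0),
                           edge_softness = 1.0) {
  stopifnot(aperture_halfwidth > 0, aperture_halfheight > 0,
            length(aperture_center) == 2, all(wedge_extent >= 0),
            all(wedge_protrusion >= 0), all(wedge_softness > 0),
            edge_softness > 0,
            length(wedge_extent) == length(wedge_angle),
            length(wedge_protrusion) == length(wedge_angle),
            length(wedge_softness) == length(wedge_angle))
  structure(list(
    aperture_halfwidth = aperture_halfwidth,
    aperture_halfheight = aperture_halfheight,
    aperture_center = aperture_center,
    standoff = standoff,
    wedge_angle = wedge_angle,
    wedge_extent = wedge_extent,
    wedge_protrusion = wedge_protrusion,
    wedge_softness = wedge_softness,
    edge_softness = edge_softness
  ), class = "occluder_model")
}

# Acoustic transmission of the aperture at an (x, y) point in the shell
# plane, vectorized. Each edge (the ellipse and every wedge) contributes a
# linear penumbra ramp: 1 inside its (narrowed) boundary, 0 at `softness`
# beyond it; the total transmission is the most restrictive edge's value.
# T = 1: fully open; 0 < T < 1: penumbra (rays pass, amplitude scaled by T);
# T = 0: geometric shadow (rays reflect off the shell).
aperture_transmission <- function(occ, x, y) {
  dx <- x - occ$aperture_center[1]
  dy <- y - occ$aperture_center[2]
  ang <- atan2(dy, dx) / DEG
  r <- sqrt(dx^2 + dy^2)
  a <- occ$aperture_halfwidth
  b <- occ$aperture_halfheight
  r_edge <- a * b / sqrt((b * cos(ang * DEG))^2 + (a * sin(ang * DEG))^2)
  Tt <- pmin(1, pmax(0, (r_edge + occ$edge_softness - r) / occ$edge_softness))
  for (i in seq_along(occ$wedge_angle)) {
    dang <- abs(((ang - occ$wedge_angle[i] + 180) %% 360) - 180)
    edge <- pmax(r_edge - occ$wedge_protrusion[i], 0)
    tw <- pmin(1, pmax(0, (edge + occ$wedge_softness[i] - r) /
                            occ$wedge_softness[i]))
    Tt <- pmin(Tt, ifelse(dang <= occ$wedge_extent[i] / 2, tw, 1))
  }
  Tt
}

# Fully open (transmission 1) test, used for scene queries.
aperture_open <- function(occ, x, y) aperture_transmission(occ, x, y) > 0

#' Single transducer
#'
#' @param position 3-vector, mm.
#' @param direction Unit aim vector (normalized internally).
#' @param mode `"transmit"` or `"receive"`.
#' @param aperture_radius Detection disc radius, mm.
#' @param acceptance_half_angle Directivity cutoff, degrees.
#' @return An object of class `transducer`.
#' @export
transducer <- function(position, direction, mode = c("transmit", "receive"),
                       aperture_radius = 0.5, acceptance_half_angle = 15) {
  mode <- match.arg(mode)
  stopifnot(length(position) == 3, length(direction) == 3,
            aperture_radius > 0, acceptance_half_angle > 0)
  structure(list(position = as.numeric(position),
                 direction = unitize(as.numeric(direction)),
                 mode = mode,
                 aperture_radius = aperture_radius,
                 acceptance_half_angle = acceptance_half_angle),
            class = "transducer")
}

#' Transducer ring around the optical axis
#'
#' Transducers sit on a circle of radius `ring_radius` in the plane
#' z = apex + `standoff`, at the given angular positions (degrees from +x,
#' the nasal direction, with positive angles toward -y; equivalently
#' counter-clockwise as seen from the eye looking out), all aimed at the
#' eye-side axis point (the rest-pose corneal apex). With the receiver fixed
#' at 180 degrees, transmitter arc positions +90/-90 sit below/above the
#' eye respectively.
#'
#' @param angles_deg Angular positions, degrees; unique modulo 360.
#' @param ring_radius Ring radius, mm.
#' @param standoff Ring plane distance from the rest corneal apex, mm.
#' @param apex_z z of the rest corneal apex (offset + cornea radius), mm.
#' @param aperture_radius,acceptance_half_angle Passed to [transducer()].
#' @return An object of class `transducer_ring`: list with the ring geometry
#'   and a `positions` data.frame.
#' @export
transducer_ring <- function(angles_deg, ring_radius = 15, standoff = 25,
                            apex_z = 13.4, aperture_radius = 0.5,
                            acceptance_half_angle = 15) {
  if (anyDuplicated(round(angles_deg %% 360, 9)))
    stop("ring angular positions must be unique modulo 360")
  z <- apex_z + standoff
  aim <- c(0, 0, apex_z)
  pos <- data.frame(angle_deg = angles_deg,
                    x = ring_radius * cos(angles_deg * DEG),
                    y = -ring_radius * sin(angles_deg * DEG),
                    z = z)
  structure(list(positions = pos, ring_radius = ring_radius,
                 standoff = standoff, apex_z = apex_z, aim_point = aim,
                 aperture_radius = aperture_radius,
                 acceptance_half_angle = acceptance_half_angle),
            class = "transducer_ring")
}

#' Extract one transducer from a ring
#'
#' @param ring A [transducer_ring()].
#' @param angle_deg Angular position on the ring.
#' @param mode `"transmit"` or `"receive"`.
#' @export
ring_transducer <- function(ring, angle_deg, mode = "transmit") {
  i <- match(angle_deg, ring$positions$angle_deg)
  if (is.na(i)) stop("no transducer at ring angle ", angle_deg)
  p <- as.numeric(ring$positions[i, c("x", "y", "z")])
  transducer(p, ring$aim_point - p, mode = mode,
             aperture_radius = ring$aperture_radius,
             acceptance_half_angle = ring$acceptance_half_angle)
}

#' Assemble a scene
#'
#' Builds the reflective surface set for a posed eye: the scleral sphere, the
#' corneal cap (portion of the corneal sphere outside the scleral sphere),
#' and optionally the occluder shell.
#'
#' @param eye An [eye_model()] (carries the gaze pose).
#' @param occluder An [occluder_model()] or `NULL` for the open-eye control.
#' @param mechanical_range Maximum allowed |gaze| per axis, degrees.
#' @return An object of class `scene`.
#' @export
make_scene <- function(eye, occluder = NULL, mechanical_range = 35) {
  stopifnot(inherits(eye, "eye_model"))
  if (any(abs(eye$gaze) > mechanical_range))
    stop("gaze pose outside the mechanical range of +/-", mechanical_range,
         " degrees")
  if (!is.null(occluder)) {
    stopifnot(inherits(occluder, "occluder_model"))
    if (occluder$standoff <= eye$sclera_radius)
      stop("occluder shell must lie strictly outside the scleral sphere")
  }
  structure(list(eye = eye, occluder = occluder), class = "scene")
}

#' Flat-plate target scene
#'
#' A single infinite reflective plane z = `distance_mm`, the target of the
#' attenuation test bench (a plate on a translation stage facing a
#' transducer pair at the origin plane).
#'
#' @param distance_mm Plate distance from the transducer plane (z = 0), mm.
#' @return An object of class `scene`.
#' @export
plate_scene <- function(distance_mm) {
  stopifnot(distance_mm > 0)
  structure(list(eye = NULL, occluder = NULL, plate_z = distance_mm),
            class = "scene")
}

# Vectorized ray-sphere parameter: smallest root > T_MIN satisfying `valid`
# at the hit point, else Inf. O, D are n x 3; valid(point_matrix) -> logical.
sphere_hit_t <- function(O, D, center, radius, valid = NULL) {
  oc <- sweep(O, 2, center)
  b <- rowSums(oc * D)
  cc <- rowSums(oc * oc) - radius^2
  disc <- b^2 - cc
  # tangent rays (disc ~ 0 within tolerance) resolve to a hit
  tol <- (GEOM_RTOL * radius)^2
  disc[disc < 0 & disc > -tol] <- 0
  t <- rep(Inf, nrow(O))
  ok <- disc >= 0
  if (!any(ok)) return(t)
  sq <- sqrt(disc[ok])
  t1 <- -b[ok] - sq
  t2 <- -b[ok] + sq
  pick <- function(tc) {
    res <- rep(Inf, length(tc))
    fin <- tc > T_MIN
    if (any(fin) && !is.null(valid)) {
      idx <- which(ok)[fin]
      P <- O[idx, , drop = FALSE] + tc[fin] * D[idx, , drop = FALSE]
      fin[fin] <- valid(P)
    }
    res[fin] <- tc[fin]
    res
  }
  cand1 <- pick(t1)
  cand2 <- pick(t2)
  t[ok] <- pmin(cand1, cand2)
  t
}

# Vectorized intersection of rays with every scene surface.
# Returns list(t, point, normal, surface) with one row/element per ray;
# t = Inf and surface = NA where nothing is hit.
scene_intersect <- function(O, D, scene) {
  n <- nrow(O)
  eye <- scene$eye
  t_best <- rep(Inf, n)
  sid <- rep(NA_character_, n)

  if (!is.null(scene$plate_z)) {
    dz <- D[, 3]
    t_p <- ifelse(abs(dz) > 0, (scene$plate_z - O[, 3]) / dz, Inf)
    t_p[t_p <= T_MIN] <- Inf
    upd <- t_p < t_best
    t_best[upd] <- t_p[upd]
    sid[upd] <- "plate"
  }

  if (!is.null(eye)) {
  # scleral sphere, excluding the part buried under the corneal cap
  t_s <- sphere_hit_t(O, D, eye$sclera_center, eye$sclera_radius,
    valid = function(P) {
      d2 <- rowSums(sweep(P, 2, eye$cornea_center)^2)
      d2 >= (eye$cornea_radius * (1 - GEOM_RTOL))^2
    })
  upd <- t_s < t_best
  t_best[upd] <- t_s[upd]
  sid[upd] <- "sclera"

  # corneal cap: corneal sphere outside the scleral sphere
  t_c <- sphere_hit_t(O, D, eye$cornea_center, eye$cornea_radius,
    valid = function(P) {
      d2 <- rowSums(sweep(P, 2, eye$sclera_center)^2)
      d2 >= (eye$sclera_radius * (1 - GEOM_RTOL))^2
    })
  upd <- t_c < t_best
  t_best[upd] <- t_c[upd]
  sid[upd] <- "cornea"
  }

  occ <- scene$occluder
  if (!is.null(occ)) {
    dz <- D[, 3]
    t_p <- ifelse(abs(dz) > 0, (occ$standoff - O[, 3]) / dz, Inf)
    t_p[t_p <= T_MIN] <- Inf
    fin <- is.finite(t_p)
    if (any(fin)) {
      px <- O[fin, 1] + t_p[fin] * D[fin, 1]
      py <- O[fin, 2] + t_p[fin] * D[fin, 2]
      blocked <- aperture_transmission(occ, px, py) <= 0
      t_p[fin][!blocked] <- Inf
    }
    upd <- t_p < t_best
    t_best[upd] <- t_p[upd]
    sid[upd] <- "occluder"
  }

  P <- O + t_best * D
  P[!is.finite(t_best), ] <- NA_real_
  N <- matrix(NA_real_, n, 3)
  i <- which(sid %in% "sclera")
  if (length(i)) N[i, ] <- sweep(P[i, , drop = FALSE], 2, eye$sclera_center) /
    eye$sclera_radius
  i <- which(sid %in% "cornea")
  if (length(i)) N[i, ] <- sweep(P[i, , drop = FALSE], 2, eye$cornea_center) /
    eye$cornea_radius
  i <- which(sid %in% "plate")
  if (length(i)) {
    N[i, 1] <- 0
    N[i, 2] <- 0
    N[i, 3] <- ifelse(D[i, 3] > 0, -1, 1)
  }
  i <- which(sid %in% "occluder")
  if (length(i)) {
    # outward = facing the incoming ray
    N[i, 1] <- 0
    N[i, 2] <- 0
    N[i, 3] <- ifelse(D[i, 3] > 0, -1, 1)
  }
  list(t = t_best, point = P, normal = N, surface = sid)
}

#' Intersect a single ray with a scene
#'
#' Returns the nearest intersection strictly ahead of the origin, with the
#' unit outward normal and surface id, or `NULL` when nothing is hit.
#'
#' @param origin,direction Ray origin (mm) and unit direction.
#' @param scene A [make_scene()] scene.
#' @return `list(point, normal, surface, t)` or `NULL`.
#' @export
intersect_ray <- function(origin, direction, scene) {
  stopifnot(length(origin) == 3, length(direction) == 3)
  if (abs(vnorm(direction) - 1) > 1e-6)
    stop("ray direction must be unit-norm")
  h <- scene_intersect(matrix(origin, 1), matrix(direction, 1), scene)
  if (!is.finite(h$t[1])) return(NULL)
  list(point = as.vector(h$point[1, ]), normal = as.vector(h$normal[1, ]),
       surface = h$surface[1], t = h$t[1])
}

#' Mirror-law specular reflection
#'
#' r = d - 2 (d.n) n for unit incident direction d and unit surface normal n.
#'
#' @param incident Unit incident direction.
#' @param normal Unit surface normal.
#' @return Unit reflected direction.
#' @export
specular_reflect <- function(incident, normal) {
  incident - 2 * sum(incident * normal) * normal
}
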