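test_that("eye model validates and poses correctly", {
  eye <- eye_model()
  # corneal apex protrudes offset + r_c - r_s = 1.475 mm beyond the sclera
  expect_equal(corneal_apex(eye), c(0, 0, 13.4))
  expect_equal(corneal_apex(eye)[3] - eye$sclera_radius, 1.475)

  posed <- eye_model(gaze = c(5, 0))
  expect_equal(posed$sclera_center, eye$sclera_center)
  expect_equal(posed$sclera_radius, eye$sclera_radius)
  expect_equal(posed$cornea_radius, eye$cornea_radius)
  # cornea center rotated rigidly by 5 degrees about the sclera center
  expect_equal(sum(posed$cornea_center^2), sum(eye$cornea_center^2))
  ang <- acos(sum(posed$cornea_center * eye$cornea_center) /
                sum(eye$cornea_center^2)) * 180 / pi
  expect_equal(ang, 5, tolerance = 1e-9)

  expect_error(eye_model(cornea_offset = 1), "protrude")
  expect_error(make_scene(eye_model(gaze = c(40, 0))), "mechanical range")
})

test_that("gaze rotation is rigid and oriented as documented", {
  pts <- rbind(c(0, 0, 11.925), c(3, 4, 10), c(-2, 1, 11))
  rot <- gaze_rotation(4, -3)
  rpts <- t(rot %*% t(pts))
  expect_equal(as.vector(dist(rpts)), as.vector(dist(pts)))
  # positive theta tips the axis nasally (+x), positive phi up (+y)
  expect_gt(gaze_rotation(5, 0)[1, 3], 0)
  expect_gt(as.vector(gaze_rotation(0, 5) %*% c(0, 0, 1))[2], 0)
})

test_that("ray-scene intersection returns the nearest hit with unit normal", {
  sc <- make_scene(eye_model())
  h <- intersect_ray(c(0, 0, 100), c(0, 0, -1), sc)
  expect_equal(h$point, c(0, 0, 13.4))
  expect_equal(h$normal, c(0, 0, 1))
  expect_equal(h$surface, "cornea")

  # from behind, the nearest surface is the sclera
  h2 <- intersect_ray(c(0, 0, -100), c(0, 0, 1), sc)
  expect_equal(h2$point, c(0, 0, -11.925))
  expect_equal(h2$surface, "sclera")

  # ray pointing away
  expect_null(intersect_ray(c(0, 0, 100), c(0, 0, 1), sc))
  expect_error(intersect_ray(c(0, 0, 100), c(0, 0, -2), sc), "unit-norm")
})

test_that("hits satisfy their surface equation and tangent rays hit", {
  sc <- make_scene(eye_model(gaze = c(3, -2)))
  set.seed(4)
  for (i in 1:50) {
    o <- c(20 * runif(1, -1, 1), 20 * runif(1, -1, 1), 60)
    d <- c(0.2 * runif(1, -1, 1), 0.2 * runif(1, -1, 1), -1)
    d <- d / sqrt(sum(d^2))
    h <- intersect_ray(o, d, sc)
    if (is.null(h)) next
    expect_equal(sqrt(sum(h$normal^2)), 1, tolerance = 1e-12)
    r <- if (h$surface == "cornea") sc$eye$cornea_radius else
      sc$eye$sclera_radius
    ctr <- if (h$surface == "cornea") sc$eye$cornea_center else
      sc$eye$sclera_center
    expect_lt(abs(sqrt(sum((h$point - ctr)^2)) - r), 1e-9 * r)
  }
  # tangent ray at exactly the scleral radius resolves to a hit
  sc0 <- make_scene(eye_model())
  ht <- intersect_ray(c(11.925, 0, -50), c(0, 0, 1), sc0)
  expect_false(is.null(ht))
})

test_that("specular reflection obeys the mirror law and is involutive", {
  expect_equal(specular_reflect(c(0, 0, -1), c(0, 0, 1)), c(0, 0, 1))
  expect_equal(specular_reflect(c(1, 0, -1) / sqrt(2), c(0, 0, 1)),
               c(1, 0, 1) / sqrt(2))
  set.seed(7)
  for (i in 1:25) {
    d <- rnorm(3); d <- d / sqrt(sum(d^2))
    n <- rnorm(3); n <- n / sqrt(sum(n^2))
    if (sum(d * n) > 0) d <- -d
    r <- specular_reflect(d, n)
    expect_equal(sqrt(sum(r^2)), 1, tolerance = 1e-12)
    expect_equal(sum(d * n), -sum(r * n), tolerance = 1e-12)
    expect_equal(specular_reflect(-r, n), -d, tolerance = 1e-12)
  }
})

test_that("occluder aperture and wedges block as parameterized", {
  occ <- occluder_model()
  sc <- make_scene(eye_model(), occ)
  # aperture exposes the corneal apex at rest gaze: axial ray reaches cornea
  h <- intersect_ray(c(0, 0, 100), c(0, 0, -1), sc)
  expect_equal(h$surface, "cornea")
  # far off-axis ray meets the shell first
  h2 <- intersect_ray(c(8, 0, 100), c(0, 0, -1), sc)
  expect_equal(h2$surface, "occluder")
  expect_equal(h2$point[3], occ$standoff)
  # wedge narrows the aperture inside its sector only: at the same radius a
  # point inside the wedge sector sits in the penumbra (transmission < 1)
  # while the unwedged nasal direction is fully open
  r_probe <- occ$aperture_halfwidth - 1.3
  ang <- occ$wedge_angle[1] * pi / 180
  x_in <- occ$aperture_center[1] + r_probe * cos(ang)
  y_in <- occ$aperture_center[2] + r_probe * sin(ang)
  t_wedge <- aperture_transmission(occ, x_in, y_in)
  expect_lt(t_wedge, 1)
  expect_equal(aperture_transmission(occ, occ$aperture_center[1] + r_probe,
                                     occ$aperture_center[2]), 1)
  # deep inside the wedge the shadow is total
  r_deep <- occ$aperture_halfwidth + 0.5
  expect_false(aperture_open(occ, occ$aperture_center[1] + r_deep * cos(ang),
                             occ$aperture_center[2] + r_deep * sin(ang)))
  # shell must be strictly outside the sclera
  expect_error(make_scene(eye_model(), occluder_model(standoff = 11)),
               "outside the scleral sphere")
  # open-eye control: no occluder surface reported
  h3 <- intersect_ray(c(8, 0, 100), c(0, 0, -1), make_scene(eye_model()))
  expect_true(is.null(h3) || h3$surface != "occluder")
})

test_that("transducer ring places and aims transducers", {
  ring <- transducer_ring(c(seq(-90, 90, 10), 180), ring_radius = 15,
                          standoff = 25)
  expect_error(transducer_ring(c(0, 360)), "unique")
  rx <- ring_transducer(ring, 180, "receive")
  expect_equal(rx$position[1], -15)
  expect_equal(rx$position[3], 38.4)
  expect_equal(sqrt(sum(rx$direction^2)), 1)
  # aims at the eye-side axis point
  aim <- ring$aim_point - rx$position
  expect_equal(rx$direction, aim / sqrt(sum(aim^2)))
  expect_error(ring_transducer(ring, 45), "no transducer")
})
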