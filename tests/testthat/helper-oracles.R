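# Independent oracles used to check the ray tracer and the signal chain.

# Analytic specular-point solver for a sphere: the reflection point of a
# transmitter-receiver pair off a sphere lies in the plane through the two
# transducers and the center; parametrize the great-circle arc between the
# two and solve the equal-angles condition by root finding. Entirely
# independent of the package's tracer.
specular_point_sphere <- function(tx, rx, center = c(0, 0, 0), radius) {
  u <- (tx - center) / sqrt(sum((tx - center)^2))
  w <- (rx - center) - sum((rx - center) * u) * u
  v <- w / sqrt(sum(w^2))
  ang_rx <- atan2(sum((rx - center) * v), sum((rx - center) * u))
  cacos <- function(x) acos(pmin(1, pmax(-1, x)))
  g <- function(phi) {
    p <- center + radius * (cos(phi) * u + sin(phi) * v)
    n <- (p - center) / radius
    d1 <- tx - p
    d2 <- rx - p
    a1 <- cacos(sum(d1 * n) / sqrt(sum(d1^2)))
    a2 <- cacos(sum(d2 * n) / sqrt(sum(d2^2)))
    a1 - a2
  }
  phi <- stats::uniroot(g, c(1e-9, ang_rx - 1e-9), tol = 1e-14)$root
  p <- center + radius * (cos(phi) * u + sin(phi) * v)
  list(point = p,
       path_mm = sqrt(sum((tx - p)^2)) + sqrt(sum((rx - p)^2)))
}

# Hemisphere average of a function of direction by 2-D quadrature (uniform
# solid-angle measure), for checking Monte-Carlo emission sampling.
hemisphere_mean <- function(f, n_cos = 400, n_az = 400) {
  cz <- (seq_len(n_cos) - 0.5) / n_cos          # cos(polar) uniform on (0,1)
  az <- 2 * pi * (seq_len(n_az) - 0.5) / n_az
  vals <- outer(cz, az, function(c, a) {
    sz <- sqrt(1 - c^2)
    f(c, sz * cos(a), sz * sin(a))
  })
  mean(vals)
}

# L1 distance between two unit-normalized receiver histograms on a common
# time grid.
histogram_l1 <- function(h1, h2, bin_us) {
  if (nrow(h1) == 0 || nrow(h2) == 0) return(NA_real_)
  bins <- seq(0, max(h1$bin_start_us, h2$bin_start_us), by = bin_us)
  w1 <- w2 <- numeric(length(bins))
  w1[match(h1$bin_start_us, bins)] <- h1$weight
  w2[match(h2$bin_start_us, bins)] <- h2$weight
  sum(abs(w1 / sum(w1) - w2 / sum(w2)))
}
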