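# Shared fixtures: compact phantoms for unit tests, synthetic single-tissue
# images, and independent geometry oracles kept deliberately separate from
# the package's own implementations.

# Small fast phantom: 128 px grid at 3 mm spacing (384 mm field of view).
small_spec <- function(...) {
  args <- utils::modifyList(list(
    grid = c(128, 128), pixel_spacing = c(3, 3), body_radii = c(150, 110),
    sat_thickness_mm = 24, muscle_thickness_mm = 12, seed = 11L), list(...))
  do.call(phantom_spec, args)
}

# Noise-free variant for exact-threshold checks.
clean_spec <- function(...) small_spec(noise_sd = c(ct = 0, mr = 0),
                                       mr_bias_amplitude = 0, ...)

# A bare CT image from a pixel matrix, spacing 1 mm.
ct_image <- function(px, spacing = c(1, 1), id = "test-ct")
  abdominal_image(px, "CT", spacing, source_id = id)

mr_image <- function(px, spacing = c(1, 1), id = "test-mr",
                     bias_corrected = TRUE)
  abdominal_image(px, "MR", spacing, source_id = id,
                  bias_corrected = bias_corrected)

# Centred disc indicator matrix (radius in px).
disc_mask <- function(n, radius, centre = (n + 1) / 2) {
  d <- sqrt(outer((seq_len(n) - centre)^2, (seq_len(n) - centre)^2, "+"))
  d <= radius
}

# Circle contour for snake initialisation.
circle_contour <- function(centre, radius, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  contour(cbind(centre + radius * sin(th), centre + radius * cos(th)))
}

# Independent point-in-polygon oracle: winding-number accumulation of
# signed angles (different algorithm from the package's even-odd crossing).
oracle_in_polygon <- function(row, col, poly) {
  vapply(seq_along(row), function(k) {
    dy <- poly[, 1] - row[k]; dx <- poly[, 2] - col[k]
    a <- atan2(dy, dx)
    da <- diff(c(a, a[1]))
    da <- ifelse(da > pi, da - 2 * pi, ifelse(da < -pi, da + 2 * pi, da))
    abs(sum(da)) > pi
  }, TRUE)
}

# Mean radial distance of contour points from a centre.
contour_radii <- function(ctr, centre) {
  sqrt((ctr$points[, 1] - centre[1])^2 + (ctr$points[, 2] - centre[2])^2)
}

dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
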