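test_that("snake locks onto a circular edge from a larger initialisation", {
  n <- 200
  edge <- adipoquant:::edge_map_from(disc_mask(n, 60) * 1, sigma = 2)
  init <- circle_contour((n + 1) / 2, 80)
  fit <- evolve_snake(init, edge, snake_params(balloon = -0.3))
  radii <- contour_radii(fit, c((n + 1) / 2, (n + 1) / 2))
  expect_lte(mean(abs(radii - 60)), 1.5)
})

test_that("enclosed area strictly decreases under inward balloon with no edges", {
  n <- 128
  zero_map <- matrix(0, n, n)
  p <- snake_params(balloon = -0.3, max_iter = 1, tol = 1e-9,
                    refine_iter = 0, n_points = 100)
  cur <- circle_contour((n + 1) / 2, 40, n = 100)
  areas <- contour_area(cur)
  for (i in 1:12) {
    cur <- evolve_snake(cur, zero_map, p)
    areas <- c(areas, contour_area(cur))
  }
  expect_true(all(diff(areas) < 0))
})

test_that("zero balloon with smoothing alone shrinks toward the centroid", {
  n <- 128
  p <- snake_params(balloon = 0, alpha = 0.2, beta = 0.5, max_iter = 50,
                    tol = 1e-9, n_points = 100)
  init <- circle_contour((n + 1) / 2, 40, n = 100)
  out <- evolve_snake(init, matrix(0, n, n), p)
  expect_lt(contour_area(out), contour_area(init))
})

test_that("a single iteration moves points no farther than the step bound", {
  n <- 128
  p <- snake_params(balloon = -0.5, gamma = 1, max_iter = 1, tol = 1e-9,
                    refine_iter = 0, n_points = 64)
  init <- circle_contour((n + 1) / 2, 40, n = 64)
  out <- evolve_snake(init, matrix(0, n, n), p)
  d <- sqrt(rowSums((out$points - init$points)^2))
  # gamma * |balloon| plus a small internal-energy/resampling allowance
  expect_lt(max(d), p$gamma * abs(p$balloon) + 0.15)
  expect_error(snake_params(max_iter = 0), "max_iter")
  expect_error(snake_params(tol = 0), "tol")
  expect_error(snake_params(gamma = 0), "gamma")
})

test_that("snake collapses with an error when nothing stops it", {
  n <- 96
  p <- snake_params(balloon = -1, max_iter = 500, tol = 1e-9,
                    refine_iter = 0, n_points = 64)
  expect_error(evolve_snake(circle_contour((n + 1) / 2, 30, n = 64),
                            matrix(0, n, n), p), "collapsed")
})

test_that("outer contour recovers the analytic ellipse area", {
  spec <- clean_spec()
  ph <- generate_phantom(spec, "CT")
  body <- compute_body_mask(ph$image)
  outer <- detect_outer_contour(ph$image, body)
  paw <- prod(spec$pixel_spacing) / 100
  analytic <- pi * prod(spec$body_radii) / 100
  expect_lt(abs(contour_area(outer) * paw - analytic) / analytic, 0.02)
  # the contour encloses essentially the whole body mask
  inside <- contour_mask(outer, nrow(ph$image$pixels), ncol(ph$image$pixels))
  expect_gte(sum(inside & body$mask) / sum(body$mask), 0.99)
})

test_that("outer contour hugs an already convex mask boundary", {
  n <- 160
  mask <- disc_mask(n, 55)
  img <- ct_image(ifelse(mask, 50, -1000))
  fit <- detect_outer_contour(img, body_mask(mask))
  radii <- contour_radii(fit, c((n + 1) / 2, (n + 1) / 2))
  expect_lt(max(abs(radii - 55)), 2)  # Hausdorff-style bound to the boundary
})

test_that("outer contour follows a concave flank indentation", {
  n <- 160
  yy <- matrix(rep(1:n, n), n); xx <- matrix(rep(1:n, each = n), n)
  disc <- (yy - 80.5)^2 + (xx - 80.5)^2 <= 60^2
  # smooth dent centred on the left boundary, ~13 px deep and 50 px tall
  dent <- ((yy - 80.5) / 25)^2 + ((xx - 20.5) / 14)^2 <= 1
  mask <- disc & !dent
  img <- ct_image(ifelse(mask, 50, -1000))
  fit <- detect_outer_contour(img, body_mask(mask),
                              snake_params(balloon = -0.3, max_iter = 800))
  hull <- adipoquant:::mask_convex_hull(mask * 1, expand_px = 0)
  expect_lt(contour_area(fit), 0.99 * contour_area(hull))
  expect_gt(contour_area(fit), 0.97 * sum(mask))
  expect_lt(contour_area(fit), 1.01 * sum(mask))
})

test_that("inner contour rests at the fat/muscle interface of a ring phantom", {
  n <- 200; ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  px <- matrix(-1000, n, n)
  px[d <= 90] <- -100            # subcutaneous fat ring 75..90
  px[d <= 75] <- 50              # muscle wall 70..75
  px[d <= 70] <- 40              # visceral cavity, no fat
  img <- ct_image(px)
  body <- compute_body_mask(img)
  outer <- detect_outer_contour(img, body)
  inner <- detect_inner_contour(img, outer, body = body)
  radii <- contour_radii(inner, c(ctr, ctr))
  expect_lt(abs(mean(radii) - 75), 2)
  expect_true(all(points_in_polygon(inner$points[, 1], inner$points[, 2],
                                    outer$points)))
})

test_that("without a subcutaneous ring the inner contour stays at the skin", {
  n <- 160; ctr <- (n + 1) / 2
  px <- ifelse(disc_mask(n, 55), 50, -1000)  # muscle only, no fat
  img <- ct_image(px)
  body <- compute_body_mask(img)
  outer <- detect_outer_contour(img, body)
  inner <- detect_inner_contour(img, outer, body = body)
  gap <- mean(contour_radii(outer, c(ctr, ctr))) -
         mean(contour_radii(inner, c(ctr, ctr)))
  expect_lt(gap, 3)
  expect_lt(contour_area(inner), contour_area(outer))
})

test_that("the solver is deterministic", {
  ph <- generate_phantom(small_spec(), "CT")
  body <- compute_body_mask(ph$image)
  a <- detect_outer_contour(ph$image, body)
  b <- detect_outer_contour(ph$image, body)
  expect_identical(a$points, b$points)
})

test_that("contour constructor enforces its invariants", {
  expect_error(contour(cbind(1:4, 1:4)), "16")
  sq <- resample_points(rbind(c(1, 1), c(1, 40), c(40, 40), c(40, 1)), 20)
  c1 <- contour(sq)
  expect_gt(adipoquant:::polygon_signed_area(c1$points), 0)  # CCW normalised
  bow <- resample_points(rbind(c(0, 0), c(30, 10), c(0, 10), c(10, 0)), 16)
  expect_error(contour(bow))  # self-intersecting or degenerate area
})
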