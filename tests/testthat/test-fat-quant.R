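test_that("CT fat window is inclusive at both ends", {
  px <- matrix(c(-191, -190, -189, -46, -45, -44, 0, -100), 2, 4)
  body <- body_mask(matrix(TRUE, 2, 4))
  fat <- classify_fat(ct_image(px), default_threshold_spec("CT"), body)
  expect_identical(as.vector(fat),
                   c(FALSE, TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, TRUE))
})

test_that("noiseless phantoms classify exactly as rendered", {
  spec <- clean_spec()
  ct <- generate_phantom(spec, "CT")
  body <- body_mask(ct$truth$body_mask)
  fat_ct <- classify_fat(ct$image, default_threshold_spec("CT"), body)
  rendered <- ct$truth$sat_mask | ct$truth$vat_mask | ct$truth$confounder_mask
  expect_identical(fat_ct, rendered)

  mr <- generate_phantom(spec, "MR")
  fat_mr <- classify_fat(mr$image, default_threshold_spec("MR"), body)
  expect_identical(fat_mr, rendered)
})

test_that("modality/spec mismatch is an error", {
  img <- ct_image(matrix(-100, 8, 8))
  expect_error(classify_fat(img, default_threshold_spec("MR"),
                            body_mask(matrix(TRUE, 8, 8))), "CT")
})

test_that("contour rasterisation agrees with a winding-number oracle", {
  set.seed(21)
  for (rep in 1:3) {
    th <- seq(0, 2 * pi, length.out = 33)[-33]
    r <- runif(32, 8, 20)
    # star-shaped polygon: simple by construction
    poly <- cbind(25 + r * sin(th), 25 + r * cos(th))
    ctr <- contour(poly)
    m <- contour_mask(ctr, 50, 50)
    grid_r <- rep(1:50, times = 50); grid_c <- rep(1:50, each = 50)
    oracle <- matrix(FALSE, 50, 50)
    oracle[cbind(grid_r, grid_c)] <-
      oracle_in_polygon(grid_r, grid_c, ctr$points)
    # pixel centres numerically on an edge may differ; interior must agree
    expect_lt(sum(m != oracle), 3)
  }
})

test_that("partition splits fat by pixel-centre containment", {
  outer <- circle_contour(50.5, 40, n = 64)
  inner <- circle_contour(50.5, 20, n = 64)
  wc <- wall_contours(outer, inner)

  none <- partition_sat_vat(matrix(FALSE, 100, 100), wc)
  expect_equal(sum(none$sat) + sum(none$vat), 0)

  ring <- disc_mask(100, 35, 50.5) & !disc_mask(100, 25, 50.5)
  pr <- partition_sat_vat(ring, wc)
  expect_identical(pr$sat, ring)
  expect_equal(sum(pr$vat), 0)

  blob <- disc_mask(100, 8, 50.5)
  blob_off <- matrix(FALSE, 100, 100)
  blob_off[31:70, 61:90] <- disc_mask(100, 12, 50.5)[31:70, 41:70]
  straddle <- blob_off  # crosses the inner circle at radius 20
  ps <- partition_sat_vat(straddle, wc)
  grid <- which(straddle, arr.ind = TRUE)
  in_inner <- oracle_in_polygon(grid[, 1], grid[, 2], inner$points)
  expect_equal(sum(ps$vat), sum(in_inner))
  expect_equal(sum(ps$sat), sum(!in_inner))
  expect_false(any(ps$sat & ps$vat))
})

test_that("fat outside the outer contour is discarded", {
  outer <- circle_contour(30.5, 15, n = 32)
  inner <- circle_contour(30.5, 6, n = 32)
  fat <- matrix(TRUE, 60, 60)
  pr <- partition_sat_vat(fat, wall_contours(outer, inner))
  outside <- !contour_mask(outer, 60, 60)
  expect_equal(sum((pr$sat | pr$vat) & outside), 0)
})

test_that("areas convert pixel counts and polygons to cm^2", {
  sat <- matrix(FALSE, 120, 120); sat[1:10, 1:10] <- TRUE  # 100 px
  vat <- matrix(FALSE, 120, 120)
  outer <- contour(resample_points(
    rbind(c(10.5, 10.5), c(10.5, 110.5), c(110.5, 110.5), c(110.5, 10.5)), 40))
  inner <- contour(resample_points(
    rbind(c(30, 30), c(30, 90), c(90, 90), c(90, 30)), 40))
  wc <- wall_contours(outer, inner)
  masks <- fat_masks(sat, vat)

  r1 <- compute_areas(masks, wc, c(1, 1), "CT", "a")
  expect_equal(r1$sat_area_cm2, 1.00)
  expect_equal(r1$outer_area_cm2, 100.0)  # shoelace on a 100 x 100 square

  r2 <- compute_areas(masks, wc, c(1.40625, 1.40625), "CT", "a")
  expect_equal(r2$sat_area_cm2, 100 * 1.40625^2 / 100, tolerance = 1e-12)
})

test_that("shrinking the CT window never grows the fat area", {
  ph <- generate_phantom(small_spec(), "CT")
  body <- compute_body_mask(ph$image)
  wide <- classify_fat(ph$image, threshold_spec("CT", -190, -45), body)
  narrow <- classify_fat(ph$image, threshold_spec("CT", -190, -50), body)
  expect_true(all(narrow <= wide))
  expect_lte(sum(narrow), sum(wide))
})

test_that("quantification is deterministic end to end and conserves fat", {
  ph <- generate_phantom(small_spec(), "CT")
  q1 <- quantify_slice(ph$image)
  q2 <- quantify_slice(ph$image)
  expect_identical(q1$masks$sat, q2$masks$sat)
  expect_identical(q1$masks$vat, q2$masks$vat)
  expect_identical(q1$contours$outer$points, q2$contours$outer$points)
  # SAT + VAT never exceeds the classified fat within the body
  expect_lte(sum(q1$masks$sat) + sum(q1$masks$vat), sum(q1$fat))
})

test_that("a phantom with no visceral fat yields zero VAT", {
  ph <- generate_phantom(small_spec(visceral_blobs = list(),
                                    spine_confounder = FALSE), "CT")
  q <- quantify_slice(ph$image)
  paw <- prod(ph$image$pixel_spacing) / 100
  expect_lte(q$result$vat_area_cm2, paw)  # at most one pixel's area
  expect_equal(ph$truth$vat_area_cm2, 0)
})

test_that("stage errors are labelled with the failing stage", {
  img <- ct_image(matrix(-1000, 64, 64))
  expect_error(quantify_slice(img), "\\[body_mask\\]")
})
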