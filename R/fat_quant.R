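# Fat-pixel classification, SAT/VAT partition by contour containment, and
# area quantification. SAT is the classified fat between the outer and inner
# contours; VAT the classified fat inside the inner contour. Fat pixels
# outside the outer contour (skin-surface partial volume) are discarded.

#' Disjoint SAT and VAT pixel masks
#' @param sat,vat Logical matrices of equal dimension with empty overlap.
#' @return An object of class \code{fat_masks}.
#' @export
fat_masks <- function(sat, vat) {
  if (!all(dim(sat) == dim(vat))) stop("sat and vat grids differ in size")
  sat <- sat != 0; vat <- vat != 0
  if (any(sat & vat)) stop("sat and vat masks must be disjoint")
  structure(list(sat = sat, vat = vat), class = "fat_masks")
}

#' @export
print.fat_masks <- function(x, ...) {
  cat(sprintf("<fat_masks> SAT %d px, VAT %d px\n", sum(x$sat), sum(x$vat)))
  invisible(x)
}

#' Classify fat pixels by the modality's intensity rule
#'
#' CT: pixels within the Hounsfield fat window (default -190 to -45 HU,
#' inclusive on both ends) inside the body mask. MR: pixels at or above the
#' fraction-of-robust-maximum threshold inside the body mask.
#'
#' @param image An \code{\link{abdominal_image}} (MR must be bias-corrected
#'   for the threshold to be meaningful).
#' @param spec A \code{\link{threshold_spec}} matching the image modality.
#' @param body A \code{\link{body_mask}} restricting the classification.
#' @return Logical matrix of fat pixels.
#' @export
classify_fat <- function(image, spec = default_threshold_spec(image$modality),
                         body) {
  stop_if_not_image(image)
  if (!inherits(spec, "threshold_spec")) stop("spec must be a threshold_spec")
  if (spec$modality != image$modality)
    stop("threshold spec is for ", spec$modality, " but image is ",
         image$modality)
  mask <- if (inherits(body, "body_mask")) body$mask else body != 0
  px <- image$pixels
  if (spec$basis == "fraction_of_max") {
    thr <- mr_fat_threshold(image, mask, spec$fraction, spec$robust_percentile)
    mask & px >= thr
  } else {
    mask & px >= spec$lower & px <= spec$upper
  }
}

#' Partition classified fat into SAT and VAT by contour containment
#'
#' Pixel membership is decided by a point-in-polygon test of the pixel
#' centre. SAT = fat inside the outer polygon but not the inner; VAT = fat
#' inside the inner polygon; fat outside the outer polygon is discarded.
#'
#' @param fat Logical fat-classification grid.
#' @param contours A \code{\link{wall_contours}} pair on the same grid.
#' @return A \code{\link{fat_masks}} object.
#' @export
partition_sat_vat <- function(fat, contours) {
  if (!inherits(contours, "wall_contours"))
    stop("contours must be a wall_contours object")
  nr <- nrow(fat); nc <- ncol(fat)
  in_outer <- contour_mask(contours$outer, nr, nc)
  in_inner <- contour_mask(contours$inner, nr, nc)
  fat_masks(sat = fat & in_outer & !in_inner, vat = fat & in_inner)
}

#' Convert masks and contours to areas in cm^2
#'
#' Mask areas are pixel counts times the pixel area; contour areas come from
#' the shoelace formula on the polygon, scaled by the pixel area. One pixel
#' is \code{row_mm x col_mm / 100} cm^2.
#'
#' @param masks A \code{\link{fat_masks}} object.
#' @param contours A \code{\link{wall_contours}} pair.
#' @param pixel_spacing \code{c(row_mm, col_mm)}.
#' @param modality,source_id Carried into the result.
#' @return A \code{\link{quant_result}}.
#' @export
compute_areas <- function(masks, contours, pixel_spacing,
                          modality = "CT", source_id = "unknown") {
  paw <- pixel_spacing[1] * pixel_spacing[2] / 100  # cm^2 per pixel
  boundary_tol <- contour_perimeter(contours$outer) * paw
  quant_result(
    outer_area_cm2 = contour_area(contours$outer) * paw,
    inner_area_cm2 = contour_area(contours$inner) * paw,
    sat_area_cm2 = sum(masks$sat) * paw,
    vat_area_cm2 = sum(masks$vat) * paw,
    modality = modality, source_id = source_id,
    boundary_tol_cm2 = boundary_tol)
}

#' Quantify one axial slice end to end
#'
#' Runs the full pipeline: MR bias correction (if needed), body-mask
#' extraction, outer then inner snake contouring, fat classification,
#' SAT/VAT partition and area computation. Deterministic: two runs on the
#' same input produce identical masks and contours. Errors are labelled with
#' the pipeline stage that raised them.
#'
#' @param image An \code{\link{abdominal_image}}.
#' @param config Configuration list, see \code{\link{adipoquant_config}}.
#' @return A list with elements \code{image} (possibly bias-corrected),
#'   \code{body}, \code{fat}, \code{contours}, \code{masks}, \code{result}.
#' @export
quantify_slice <- function(image, config = adipoquant_config()) {
  stop_if_not_image(image)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  if (image$modality == "MR" && !image$bias_corrected)
    image <- stage("bias_correction",
                   correct_bias_field(image, config$mr_bias_smoothing_mm))
  body <- stage("body_mask", compute_body_mask(image, config))
  outer <- stage("outer_contour",
                 detect_outer_contour(image, body, config$snake_outer))
  spec <- default_threshold_spec(image$modality, config)
  fat <- stage("fat_classification", classify_fat(image, spec, body))
  inner <- stage("inner_contour",
                 detect_inner_contour(image, outer, config$snake_inner,
                                      body = body, fat = fat))
  contours <- stage("contours", wall_contours(outer, inner))
  masks <- stage("partition", partition_sat_vat(fat, contours))
  result <- stage("areas", compute_areas(masks, contours, image$pixel_spacing,
                                         image$modality, image$source_id))
  list(image = image, body = body, fat = fat, contours = contours,
       masks = masks, result = result)
}
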