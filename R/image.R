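#' Construct an abdominal image
#'
#' The central container of the package: one axial abdominal slice with
#' calibrated intensities. CT pixels must be in Hounsfield units (rescale
#' slope/intercept already applied, so air is about -1000 HU); MR pixels are
#' non-negative arbitrary units from a fat-only Dixon reconstruction.
#'
#' @param pixels Numeric matrix (rows x columns) of pixel intensities.
#' @param modality Either \code{"CT"} or \code{"MR"}.
#' @param pixel_spacing Numeric length-2 vector \code{c(row_mm, col_mm)}:
#'   physical size of one pixel along the row and column directions, in mm.
#'   Must be strictly positive; areas in cm^2 are meaningless without it.
#' @param source_id Opaque identifier carried through to results.
#' @param bias_corrected Logical; \code{TRUE} once the multiplicative MR bias
#'   field has been divided out. Ignored for CT (always \code{TRUE}).
#' @return An object of class \code{abdominal_image}.
#' @export
abdominal_image <- function(pixels, modality, pixel_spacing,
                            source_id = "unknown", bias_corrected = FALSE) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("pixels must be a numeric matrix")
  modality <- match.arg(toupper(modality), c("CT", "MR"))
  pixel_spacing <- as.numeric(pixel_spacing)
  if (length(pixel_spacing) != 2 || any(!is.finite(pixel_spacing)) ||
      any(pixel_spacing <= 0))
    stop("pixel_spacing must be two strictly positive numbers (row_mm, col_mm)")
  if (modality == "MR" && min(pixels) < 0)
    stop("MR pixels must be non-negative")
  structure(list(
    pixels = pixels,
    modality = modality,
    pixel_spacing = pixel_spacing,
    source_id = as.character(source_id),
    bias_corrected = if (modality == "CT") TRUE else isTRUE(bias_corrected)
  ), class = "abdominal_image")
}

#' @export
print.abdominal_image <- function(x, ...) {
  cat(sprintf("<abdominal_image> %s %s  %dx%d px  spacing %.4gx%.4g mm%s\n",
              x$source_id, x$modality, nrow(x$pixels), ncol(x$pixels),
              x$pixel_spacing[1], x$pixel_spacing[2],
              if (x$modality == "MR")
                sprintf("  bias_corrected=%s", x$bias_corrected) else ""))
  invisible(x)
}

#' @export
dim.abdominal_image <- function(x) dim(x$pixels)

is_abdominal_image <- function(x) inherits(x, "abdominal_image")

stop_if_not_image <- function(x) {
  if (!is_abdominal_image(x)) stop("expected an abdominal_image object")
  invisible(x)
}

#' Construct a per-slice quantification result
#'
#' Holds the four areas the pipeline reports, all in cm^2: the outer (skin)
#' and inner (abdominal-wall) region areas from the traced contours, and the
#' SAT/VAT areas from the classified fat masks.
#'
#' The invariants reflect the geometry: the inner region is nested in the
#' outer, VAT lives inside the inner contour, and SAT cannot exceed the
#' annulus between the contours by more than a one-pixel band along the
#' contour (discretisation slack for pixel-centre containment).
#'
#' @param outer_area_cm2,inner_area_cm2,sat_area_cm2,vat_area_cm2 Areas, cm^2.
#' @param modality \code{"CT"} or \code{"MR"}.
#' @param source_id Identifier matching the source image.
#' @param boundary_tol_cm2 Discretisation slack for the SAT invariant,
#'   normally the area of a one-pixel-wide band along the outer contour.
#' @return An object of class \code{quant_result}.
#' @export
quant_result <- function(outer_area_cm2, inner_area_cm2, sat_area_cm2,
                         vat_area_cm2, modality, source_id = "unknown",
                         boundary_tol_cm2 = 0) {
  areas <- c(outer_area_cm2, inner_area_cm2, sat_area_cm2, vat_area_cm2)
  if (any(!is.finite(areas)) || any(areas < 0))
    stop("areas must be finite and non-negative")
  if (inner_area_cm2 > outer_area_cm2 + 1e-9)
    stop("inner_area_cm2 must not exceed outer_area_cm2")
  if (sat_area_cm2 > outer_area_cm2 - inner_area_cm2 + boundary_tol_cm2 + 1e-9)
    stop("sat_area_cm2 exceeds the annulus between outer and inner contours")
  if (vat_area_cm2 > inner_area_cm2 + 1e-9)
    stop("vat_area_cm2 must not exceed inner_area_cm2")
  structure(list(
    outer_area_cm2 = outer_area_cm2,
    inner_area_cm2 = inner_area_cm2,
    sat_area_cm2 = sat_area_cm2,
    vat_area_cm2 = vat_area_cm2,
    modality = match.arg(toupper(modality), c("CT", "MR")),
    source_id = as.character(source_id)
  ), class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf(
    "<quant_result> %s %s  outer %.1f  inner %.1f  SAT %.1f  VAT %.1f cm^2\n",
    x$source_id, x$modality, x$outer_area_cm2, x$inner_area_cm2,
    x$sat_area_cm2, x$vat_area_cm2))
  invisible(x)
}

#' Default pipeline configuration
#'
#' Returns the full set of tunable parameters with their defaults. Any subset
#' can be overridden by passing a named list to \code{\link{quantify_slice}}.
#'
#' @param ... Named overrides merged over the defaults (one level deep for the
#'   \code{snake_outer}/\code{snake_inner} sub-lists).
#' @return A named list of configuration values.
#' @export
adipoquant_config <- function(...) {
  cfg <- list(
    ct_window = c(-190, -45),        # HU fat window, inclusive both ends
    mr_fraction = 0.5,               # fraction of robust max for MR threshold
    mr_robust_percentile = 99.5,     # percentile defining the robust max
    mr_bias_smoothing_mm = 60,       # homomorphic bias-field smoothing scale
    body_erosion_mm = 8,             # inner-seed erosion / edge-suppression
    body_min_foreground_frac = 0.01, # below this the field of view has no body
    snake_outer = snake_params(balloon = -0.3),
    snake_inner = snake_params(balloon = -0.5)
  )
  over <- list(...)
  if (length(over) == 1 && is.null(names(over)) && is.list(over[[1]]))
    over <- over[[1]]
  for (nm in names(over)) {
    if (nm %in% c("snake_outer", "snake_inner")) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], over[[nm]])
      class(cfg[[nm]]) <- "snake_params"
    } else cfg[[nm]] <- over[[nm]]
  }
  cfg
}
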