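# External body-mask extraction: modality-specific intensity thresholding,
# region growing from the image centre (8-connectivity), hole filling and
# removal of scan-table components.

#' Construct a body mask object
#' @param mask Logical matrix.
#' @param kind \code{"outer_body"} or \code{"inner_seed"}.
#' @return An object of class \code{body_mask}.
#' @export
body_mask <- function(mask, kind = c("outer_body", "inner_seed")) {
  kind <- match.arg(kind)
  if (!is.matrix(mask)) stop("mask must be a matrix")
  structure(list(mask = mask != 0, kind = kind), class = "body_mask")
}

#' @export
print.body_mask <- function(x, ...) {
  cat(sprintf("<body_mask> %s, %d px foreground\n", x$kind, sum(x$mask)))
  invisible(x)
}

# 8-connected component labelling: EBImage::bwlabel (4-connectivity) plus a
# union-find merge of labels that touch diagonally.
label_components8 <- function(mask) {
  lab <- as.matrix(EBImage::bwlabel(mask * 1))
  nlab <- max(lab)
  if (nlab <= 1) return(lab)
  parent <- seq_len(nlab)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nr <- nrow(lab); nc <- ncol(lab)
  for (shift in list(c(1, 1), c(1, -1))) {
    a <- lab[1:(nr - 1), if (shift[2] == 1) 1:(nc - 1) else 2:nc]
    b <- lab[2:nr, if (shift[2] == 1) 2:nc else 1:(nc - 1)]
    touch <- which(a > 0 & b > 0 & a != b)
    for (k in touch) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_len(nlab), find, 0L)
  relab <- match(roots, sort(unique(roots)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

#' Compute the external body mask
#'
#' Thresholds the slice (CT: pixels above -190 HU; MR: pixels above the
#' configured fraction of the robust maximum intensity), labels 8-connected
#' components, discards scan-table components (touching the bottom border
#' with area under 20 percent of the largest), grows the region containing
#' the image-centre seed (falling back to the largest component when the
#' centre is background) and fills interior holes such as bowel gas.
#'
#' @param image An \code{\link{abdominal_image}}; MR input should be
#'   bias-corrected first.
#' @param config Configuration list, see \code{\link{adipoquant_config}}.
#' @return A \code{\link{body_mask}} of kind \code{outer_body}: one filled
#'   connected component.
#' @export
compute_body_mask <- function(image, config = adipoquant_config()) {
  stop_if_not_image(image)
  px <- image$pixels
  nr <- nrow(px); nc <- ncol(px)
  if (image$modality == "CT") {
    bin <- px > config$ct_window[1]
  } else {
    robust_max <- stats::quantile(px, config$mr_robust_percentile / 100,
                                  names = FALSE)
    bin <- px > config$mr_fraction * robust_max
  }
  if (sum(bin) < config$body_min_foreground_frac * nr * nc)
    stop("no body in the field of view (foreground below ",
         100 * config$body_min_foreground_frac, "% of the image)")
  lab <- label_components8(bin)
  sizes <- tabulate(lab[lab > 0])
  largest <- max(sizes)
  # scan-table removal: small components resting on the bottom image border
  for (l in which(sizes < 0.2 * largest)) {
    rows_l <- which(lab == l, arr.ind = TRUE)[, 1]
    if (max(rows_l) == nr) lab[lab == l] <- 0L
  }
  sizes <- tabulate(lab[lab > 0])
  if (length(sizes) == 0 || max(sizes) == 0)
    stop("no body in the field of view")
  fill <- function(l) as.matrix(EBImage::fillHull((lab == l) * 1)) != 0
  largest_mask <- fill(which.max(sizes))
  seed_label <- lab[round(nr / 2), round(nc / 2)]
  mask <- if (seed_label > 0) fill(seed_label) else largest_mask
  # the centre seed can land on a small interior structure (e.g. a visceral
  # fat island on fat-only MR); the body is then the dominant component
  if (sum(mask) < 0.5 * sum(largest_mask)) mask <- largest_mask
  if (sum(mask) < config$body_min_foreground_frac * nr * nc)
    stop("no body in the field of view (selected component too small)")
  body_mask(mask, "outer_body")
}

#' Erode the body mask to seed the inner-contour stage
#'
#' Erosion distance is given in millimetres and converted to pixels per axis,
#' so anisotropic pixel spacing produces an elliptical structuring element.
#'
#' @param body A \code{\link{body_mask}} of kind \code{outer_body}.
#' @param erosion_mm Erosion distance in mm; 0 returns the mask unchanged.
#' @param pixel_spacing \code{c(row_mm, col_mm)}.
#' @return A \code{\link{body_mask}} of kind \code{inner_seed}.
#' @export
inner_seed_mask <- function(body, erosion_mm, pixel_spacing) {
  if (!inherits(body, "body_mask") || body$kind != "outer_body")
    stop("body must be an outer_body mask")
  if (erosion_mm < 0) stop("erosion_mm must be >= 0")
  if (erosion_mm == 0) return(body_mask(body$mask, "inner_seed"))
  rr <- erosion_mm / pixel_spacing[1]
  rc <- erosion_mm / pixel_spacing[2]
  kr <- floor(rr); kc <- floor(rc)
  dr <- matrix(rep(-kr:kr, times = 2 * kc + 1), ncol = 2 * kc + 1)
  dc <- matrix(rep(-kc:kc, each = 2 * kr + 1), ncol = 2 * kc + 1)
  kern <- ((dr / rr)^2 + (dc / rc)^2 <= 1) * 1
  eroded <- as.matrix(EBImage::erode(body$mask * 1, kern)) != 0
  if (!any(eroded)) stop("erosion emptied the body mask")
  body_mask(eroded, "inner_seed")
}
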