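# Programmatic replacement for interactive result correction: removal of
# false-positive fat regions (spinal canal, neural foramina, intramuscular
# fat) expressed as exclusion grids, plus contour replacement with
# requantification. Editing of masks is strictly removal-only.

#' Remove false-positive fat pixels
#'
#' Clears every SAT/VAT pixel covered by the exclusion grid. Nothing is ever
#' added, so \code{sat + vat} can only shrink.
#'
#' @param masks A \code{\link{fat_masks}} object.
#' @param exclusion Logical grid of pixels to clear (same dimensions).
#' @return The edited \code{\link{fat_masks}}.
#' @export
remove_fp_regions <- function(masks, exclusion) {
  if (!inherits(masks, "fat_masks")) stop("masks must be a fat_masks object")
  if (!all(dim(exclusion) == dim(masks$sat)))
    stop("exclusion grid dimensions do not match the masks")
  keep <- !(exclusion != 0)
  fat_masks(masks$sat & keep, masks$vat & keep)
}

#' Propose an exclusion region for spine-related false positives
#'
#' Flags small fat components (below \code{max_area_cm2}) that are enclosed
#' by high-intensity bone on CT (rays from the component centroid hit
#' pixels above \code{bone_hu} in nearly all directions within
#' \code{enclosure_mm}), or whose centroid falls in a posterior midline box
#' on MR, where no bone intensity signature exists. This is an advisory
#' proposal only: the caller decides whether to apply it via
#' \code{\link{remove_fp_regions}}.
#'
#' @param image The source \code{\link{abdominal_image}}.
#' @param masks The \code{\link{fat_masks}} to screen.
#' @param max_area_cm2 Area guard: larger components are genuine fat depots
#'   and are never flagged. Default 0.3 cm^2.
#' @param bone_hu CT bone threshold, default 150 HU.
#' @param enclosure_mm Ray length for the CT bone-enclosure test.
#' @return Logical exclusion grid (possibly empty).
#' @export
auto_exclude_spine <- function(image, masks, max_area_cm2 = 0.3,
                               bone_hu = 150, enclosure_mm = 25) {
  stop_if_not_image(image)
  fat <- masks$sat | masks$vat
  nr <- nrow(fat); nc <- ncol(fat)
  excl <- matrix(FALSE, nr, nc)
  if (!any(fat)) return(excl)
  paw <- image$pixel_spacing[1] * image$pixel_spacing[2] / 100
  lab <- label_components8(fat)
  sizes <- tabulate(lab[lab > 0])
  small <- which(sizes * paw < max_area_cm2)
  if (length(small) == 0) return(excl)
  if (image$modality == "CT") {
    bone <- image$pixels > bone_hu
    steps <- max(3, ceiling(enclosure_mm / mean(image$pixel_spacing)))
    dirs <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
    for (l in small) {
      idx <- which(lab == l, arr.ind = TRUE)
      ctr <- round(colMeans(idx))
      hits <- 0
      for (d in seq_len(nrow(dirs))) {
        rr <- ctr[1] + dirs[d, 1] * seq_len(steps)
        cc <- ctr[2] + dirs[d, 2] * seq_len(steps)
        keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
        if (any(bone[cbind(rr[keep], cc[keep])])) hits <- hits + 1
      }
      if (hits >= 7) excl[lab == l] <- TRUE
    }
  } else {
    # posterior midline box: central 24% of columns, posterior image half
    col_lo <- nc / 2 - 0.12 * nc; col_hi <- nc / 2 + 0.12 * nc
    for (l in small) {
      idx <- which(lab == l, arr.ind = TRUE)
      ctr <- colMeans(idx)
      if (ctr[1] > nr / 2 && ctr[2] >= col_lo && ctr[2] <= col_hi)
        excl[lab == l] <- TRUE
    }
  }
  excl
}

#' Replace one wall contour and requantify the masks
#'
#' @param contours The current \code{\link{wall_contours}}.
#' @param which \code{"outer"} or \code{"inner"}.
#' @param new_contour The replacement \code{\link{contour}}; containment with
#'   the partner contour must still hold.
#' @param image The source image (for grid dimensions).
#' @param fat The classified fat grid to repartition.
#' @return A list with the new \code{contours} and recomputed \code{masks}.
#' @export
replace_contour <- function(contours, which = c("outer", "inner"),
                            new_contour, image, fat) {
  which <- match.arg(which)
  if (!inherits(new_contour, "contour"))
    stop("new_contour must be a contour object")
  updated <- if (which == "outer")
    wall_contours(new_contour, contours$inner)
  else
    wall_contours(contours$outer, new_contour)
  list(contours = updated, masks = partition_sat_vat(fat, updated))
}

#' Read an exclusion grid from run-length-encoded JSON
#'
#' The format is \code{{"dim": [nr, nc], "runs": [[start, length], ...]}}
#' with runs indexing the grid in column-major order, 1-based.
#'
#' @param path JSON file path.
#' @return Logical matrix.
#' @export
read_exclusion_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- matrix(FALSE, obj$dim[1], obj$dim[2])
  runs <- obj$runs
  if (length(runs)) {
    runs <- matrix(as.integer(runs), ncol = 2)
    for (i in seq_len(nrow(runs)))
      m[runs[i, 1] + seq_len(runs[i, 2]) - 1] <- TRUE
  }
  m
}

#' Write an exclusion grid as run-length-encoded JSON
#' @param mask Logical matrix.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_exclusion_json <- function(mask, path) {
  v <- as.logical(mask)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(starts[r$values], r$lengths[r$values])
  jsonlite::write_json(list(dim = dim(mask), runs = runs), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}
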