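# Minimal single-frame DICOM Part 10 support: uncompressed little-endian
# transfer syntaxes only (explicit 1.2.840.10008.1.2.1, implicit
# 1.2.840.10008.1.2). Enough to ingest scanner CT/MR axial slices and to
# export RGB secondary-capture overlays; sequences with undefined length and
# compressed pixel data are out of scope.

UID_EXPLICIT_LE <- "1.2.840.10008.1.2.1"
UID_IMPLICIT_LE <- "1.2.840.10008.1.2"
SOP_CT <- "1.2.840.10008.5.1.4.1.1.2"
SOP_MR <- "1.2.840.10008.5.1.4.1.1.4"
SOP_SC <- "1.2.840.10008.5.1.4.1.1.7"

LONG_VRS <- c("OB", "OW", "OF", "OD", "OL", "SQ", "UC", "UR", "UT", "UN")

new_uid <- function() {
  # UUID-derived numeric form under the 2.25 root
  paste0("2.25.", paste(sample(1:9, 1), collapse = ""),
         paste(sample(0:9, 30, replace = TRUE), collapse = ""))
}

tag_key <- function(group, elem) sprintf("%04X,%04X", group, elem)

# ---- encoding -------------------------------------------------------------

enc_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
enc_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

pad_even <- function(bytes, pad = as.raw(0x20)) {
  if (length(bytes) %% 2 == 1) c(bytes, pad) else bytes
}

enc_element <- function(group, elem, vr, bytes) {
  bytes <- pad_even(bytes, if (vr %in% c("UI", "OB", "OW", "UN")) as.raw(0)
                           else as.raw(0x20))
  head <- c(enc_u16(group), enc_u16(elem), charToRaw(vr))
  if (vr %in% LONG_VRS) {
    c(head, as.raw(c(0, 0)), enc_u32(length(bytes)), bytes)
  } else {
    if (length(bytes) > 65534) stop("value too long for short VR")
    c(head, enc_u16(length(bytes)), bytes)
  }
}

el_str <- function(group, elem, vr, value)
  list(group = group, elem = elem, vr = vr, bytes = charToRaw(as.character(value)))
el_us <- function(group, elem, value)
  list(group = group, elem = elem, vr = "US", bytes = enc_u16(value))
el_ds <- function(group, elem, values)
  el_str(group, elem, "DS", paste(vapply(values, function(v)
    format(v, digits = 12, scientific = FALSE, trim = TRUE), ""),
    collapse = "\\"))
el_raw <- function(group, elem, vr, bytes)
  list(group = group, elem = elem, vr = vr, bytes = bytes)

# Serialise a dataset (list of elements) as an explicit-VR-LE Part 10 file.
dcm_write_file <- function(path, sop_class, elements) {
  sop_instance <- new_uid()
  meta_elems <- list(
    el_raw(0x0002, 0x0001, "OB", as.raw(c(0, 1))),
    el_str(0x0002, 0x0002, "UI", sop_class),
    el_str(0x0002, 0x0003, "UI", sop_instance),
    el_str(0x0002, 0x0010, "UI", UID_EXPLICIT_LE),
    el_str(0x0002, 0x0012, "UI", "2.25.1416297463923357")
  )
  meta_bytes <- do.call(c, lapply(meta_elems, function(e)
    enc_element(e$group, e$elem, e$vr, e$bytes)))
  meta_bytes <- c(enc_element(0x0002, 0x0000, "UL", enc_u32(length(meta_bytes))),
                  meta_bytes)
  elements <- c(list(
    el_str(0x0008, 0x0016, "UI", sop_class),
    el_str(0x0008, 0x0018, "UI", sop_instance)
  ), elements)
  ord <- order(vapply(elements, function(e) e$group * 2^16 + e$elem, 0))
  body <- do.call(c, lapply(elements[ord], function(e)
    enc_element(e$group, e$elem, e$vr, e$bytes)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(132), con)  # preamble placeholder, then overwrite magic
  seek(con, 128)
  writeBin(charToRaw("DICM"), con)
  writeBin(c(meta_bytes, body), con)
  invisible(path)
}

# ---- decoding -------------------------------------------------------------

dec_u16 <- function(bytes, signed = FALSE)
  readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
          signed = signed, endian = "little")
dec_u32 <- function(bytes)
  readBin(bytes, "integer", n = length(bytes) / 4, size = 4, endian = "little")
dec_str <- function(bytes) {
  s <- rawToChar(bytes[bytes != as.raw(0)])
  trimws(s)
}
dec_ds <- function(bytes) as.numeric(strsplit(dec_str(bytes), "\\\\")[[1]])

# Parse one element stream; returns named list tag -> list(vr, bytes).
parse_elements <- function(bytes, explicit, stop_group = NULL) {
  out <- list()
  pos <- 1L
  n <- length(bytes)
  while (pos + 7L <= n) {
    group <- dec_u16(bytes[pos:(pos + 1L)]); elem <- dec_u16(bytes[(pos + 2L):(pos + 3L)])
    if (!is.null(stop_group) && group != stop_group) break
    pos <- pos + 4L
    if (explicit) {
      vr <- rawToChar(bytes[pos:(pos + 1L)])
      if (vr %in% LONG_VRS) {
        len <- dec_u32(bytes[(pos + 4L):(pos + 7L)]); pos <- pos + 8L
      } else {
        len <- dec_u16(bytes[(pos + 2L):(pos + 3L)]); pos <- pos + 4L
      }
    } else {
      vr <- "UN"
      len <- dec_u32(bytes[pos:(pos + 3L)]); pos <- pos + 4L
    }
    if (len < 0 || len == -1)  # 0xFFFFFFFF undefined length
      stop("undefined-length DICOM sequences are not supported")
    if (pos + len - 1L > n) stop("truncated DICOM element")
    out[[tag_key(group, elem)]] <- list(
      vr = vr, bytes = if (len > 0) bytes[pos:(pos + len - 1L)] else raw(0))
    pos <- pos + len
  }
  attr(out, "consumed") <- pos - 1L
  out
}

dcm_read_file <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 140 || rawToChar(bytes[129:132]) != "DICM")
    stop("not a DICOM Part 10 file: ", path)
  meta <- parse_elements(bytes[-(1:132)], explicit = TRUE, stop_group = 0x0002)
  ts <- meta[["0002,0010"]]
  ts <- if (is.null(ts)) UID_EXPLICIT_LE else dec_str(ts$bytes)
  if (!ts %in% c(UID_EXPLICIT_LE, UID_IMPLICIT_LE))
    stop("unsupported transfer syntax: ", ts)
  body <- bytes[-(1:(132 + attr(meta, "consumed")))]
  ds <- parse_elements(body, explicit = ts == UID_EXPLICIT_LE)
  c(meta, ds)
}

ds_str <- function(ds, tag, default = NULL) {
  e <- ds[[tag]]
  if (is.null(e)) return(default)
  dec_str(e$bytes)
}
ds_num <- function(ds, tag, default = NULL) {
  e <- ds[[tag]]
  if (is.null(e)) return(default)
  if (e$vr %in% c("US", "SS")) dec_u16(e$bytes, signed = e$vr == "SS")
  else if (e$vr %in% c("UL", "SL")) dec_u32(e$bytes)
  else {
    v <- suppressWarnings(dec_ds(e$bytes))
    # implicit VR: US tags arrive as UN 2-byte integers
    if (all(is.na(v)) && length(e$bytes) %in% c(2L, 4L))
      v <- if (length(e$bytes) == 2L) dec_u16(e$bytes) else dec_u32(e$bytes)
    v
  }
}

decode_pixels <- function(ds) {
  px <- ds[["7FE0,0010"]]
  if (is.null(px)) stop("no PixelData in file")
  bits <- ds_num(ds, "0028,0100", 16)[1]
  signed <- identical(ds_num(ds, "0028,0103", 0)[1], 1L) ||
            identical(ds_num(ds, "0028,0103", 0)[1], 1)
  rows <- ds_num(ds, "0028,0010")[1]
  cols <- ds_num(ds, "0028,0011")[1]
  spp <- ds_num(ds, "0028,0002", 1)[1]
  if (is.null(rows) || is.null(cols)) stop("missing Rows/Columns")
  nval <- rows * cols * spp
  if (bits == 8) {
    v <- as.integer(px$bytes[seq_len(nval)])
    if (signed) v <- ifelse(v > 127, v - 256L, v)
  } else {
    v <- readBin(px$bytes, "integer", n = nval, size = 2,
                 signed = signed, endian = "little")
    if (!signed) v <- ifelse(v < 0, v + 65536, v)
  }
  if (spp == 1) {
    matrix(v, nrow = rows, ncol = cols, byrow = TRUE)
  } else {
    planar <- identical(ds_num(ds, "0028,0006", 0)[1], 1L)
    arr <- array(0, dim = c(rows, cols, spp))
    if (planar) {
      for (s in seq_len(spp))
        arr[, , s] <- matrix(v[((s - 1) * rows * cols + 1):(s * rows * cols)],
                             nrow = rows, byrow = TRUE)
    } else {
      for (s in seq_len(spp))
        arr[, , s] <- matrix(v[seq(s, nval, by = spp)], nrow = rows, byrow = TRUE)
    }
    arr
  }
}

# ---- public API -----------------------------------------------------------

#' Read a single-frame CT or MR DICOM slice
#'
#' Reads an uncompressed little-endian DICOM file, applies the rescale
#' slope/intercept (so CT pixel values are Hounsfield units) and returns an
#' \code{\link{abdominal_image}}. Modality and pixel spacing are taken from
#' the file; files without pixel spacing are rejected because areas in cm^2
#' would be meaningless.
#'
#' @param path Path to a DICOM file of modality CT or MR.
#' @return An \code{\link{abdominal_image}}.
#' @export
read_slice <- function(path) {
  ds <- dcm_read_file(path)
  modality <- ds_str(ds, "0008,0060")
  if (is.null(modality) || !modality %in% c("CT", "MR"))
    stop("unsupported modality: ",
         if (is.null(modality)) "<missing>" else modality)
  spacing <- ds_num(ds, "0028,0030")
  if (is.null(spacing) || length(spacing) != 2 || any(!is.finite(spacing)))
    stop("missing PixelSpacing; cannot compute areas in cm^2")
  slope <- ds_num(ds, "0028,1053", 1)[1]
  intercept <- ds_num(ds, "0028,1052", 0)[1]
  px <- decode_pixels(ds)
  if (length(dim(px)) != 2) stop("multi-sample images are not slice inputs")
  px <- px * slope + intercept
  if (modality == "MR") px[px < 0] <- 0
  src <- ds_str(ds, "0010,0020", ds_str(ds, "0008,0018",
                basename(path)))
  abdominal_image(px, modality, spacing, source_id = src,
                  bias_corrected = FALSE)
}

#' Write an abdominal image as a single-frame DICOM slice
#'
#' Exports a CT image as 16-bit stored values with rescale intercept -1024
#' (so Hounsfield units survive the round trip), or an MR image as 16-bit
#' rounded arbitrary units. Mainly used to serialise phantoms so the full
#' file-based pipeline can be exercised.
#'
#' @param image An \code{\link{abdominal_image}}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_dicom_slice <- function(image, path) {
  stop_if_not_image(image)
  px <- image$pixels
  if (image$modality == "CT") {
    stored <- round(px) + 1024
    intercept <- -1024
  } else {
    stored <- round(px)
    intercept <- 0
  }
  stored <- pmin(pmax(stored, 0), 32767)
  sop <- if (image$modality == "CT") SOP_CT else SOP_MR
  elements <- list(
    el_str(0x0008, 0x0060, "CS", image$modality),
    el_str(0x0010, 0x0010, "PN", image$source_id),
    el_str(0x0010, 0x0020, "LO", image$source_id),
    el_str(0x0020, 0x000D, "UI", new_uid()),
    el_str(0x0020, 0x000E, "UI", new_uid()),
    el_us(0x0028, 0x0002, 1),
    el_str(0x0028, 0x0004, "CS", "MONOCHROME2"),
    el_us(0x0028, 0x0010, nrow(px)),
    el_us(0x0028, 0x0011, ncol(px)),
    el_ds(0x0028, 0x0030, image$pixel_spacing),
    el_us(0x0028, 0x0100, 16),
    el_us(0x0028, 0x0101, 16),
    el_us(0x0028, 0x0102, 15),
    el_us(0x0028, 0x0103, 0),
    el_ds(0x0028, 0x1052, intercept),
    el_ds(0x0028, 0x1053, 1),
    el_raw(0x7FE0, 0x0010, "OW",
           writeBin(as.integer(t(stored)), raw(), size = 2, endian = "little"))
  )
  dcm_write_file(path, sop, elements)
}

# Scale a grayscale slice into 0..255 using the modality display window.
# CT window [-190, 200] HU, MR [0, max]: display only, no quantification role.
display_gray <- function(image) {
  px <- image$pixels
  w <- if (image$modality == "CT") c(-190, 200) else c(0, max(px))
  if (w[2] <= w[1]) w[2] <- w[1] + 1
  g <- (px - w[1]) / (w[2] - w[1])
  round(pmin(pmax(g, 0), 1) * 255)
}

# Pixel indices covered by a closed polyline, 1-px thick.
contour_pixels <- function(contour, nr, nc) {
  pts <- contour$points
  closed <- rbind(pts, pts[1, , drop = FALSE])
  out <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(nrow(pts))) {
    p1 <- closed[i, ]; p2 <- closed[i + 1, ]
    steps <- max(2, ceiling(2 * sqrt(sum((p2 - p1)^2))))
    t <- seq(0, 1, length.out = steps)
    out <- rbind(out, cbind(p1[1] + t * (p2[1] - p1[1]),
                            p1[2] + t * (p2[2] - p1[2])))
  }
  ij <- unique(round(out))
  ij <- ij[ij[, 1] >= 1 & ij[, 1] <= nr & ij[, 2] >= 1 & ij[, 2] <= nc, ,
           drop = FALSE]
  ij
}

#' Write a segmentation overlay as an RGB secondary-capture DICOM
#'
#' Burns the result into a windowed grayscale rendering of the slice: outer
#' contour green, inner contour red, SAT mask magenta, VAT mask cyan, with
#' contours taking precedence over masks and masks over the grayscale base.
#'
#' @param image The source \code{\link{abdominal_image}}.
#' @param contours A \code{\link{wall_contours}} object on the same grid.
#' @param masks A \code{\link{fat_masks}} object on the same grid.
#' @param path Output path for the 8-bit RGB DICOM file.
#' @return The path, invisibly.
#' @export
write_secondary_capture <- function(image, contours, masks, path) {
  stop_if_not_image(image)
  nr <- nrow(image$pixels); nc <- ncol(image$pixels)
  if (!all(dim(masks$sat) == c(nr, nc)) || !all(dim(masks$vat) == c(nr, nc)))
    stop("mask dimensions do not match the image grid")
  g <- display_gray(image)
  r <- g; gr <- g; b <- g
  r[masks$sat] <- 255; gr[masks$sat] <- 0;   b[masks$sat] <- 255  # magenta
  r[masks$vat] <- 0;   gr[masks$vat] <- 255; b[masks$vat] <- 255  # cyan
  paint <- function(ij, col) {
    idx <- ij[, 1] + (ij[, 2] - 1) * nr
    r[idx] <<- col[1]; gr[idx] <<- col[2]; b[idx] <<- col[3]
  }
  paint(contour_pixels(contours$outer, nr, nc), c(0, 255, 0))   # green
  paint(contour_pixels(contours$inner, nr, nc), c(255, 0, 0))   # red
  inter <- as.integer(rbind(as.vector(t(r)), as.vector(t(gr)), as.vector(t(b))))
  elements <- list(
    el_str(0x0008, 0x0060, "CS", "OT"),
    el_str(0x0008, 0x0064, "CS", "WSD"),
    el_str(0x0010, 0x0020, "LO", image$source_id),
    el_str(0x0020, 0x000D, "UI", new_uid()),
    el_str(0x0020, 0x000E, "UI", new_uid()),
    el_us(0x0028, 0x0002, 3),
    el_str(0x0028, 0x0004, "CS", "RGB"),
    el_us(0x0028, 0x0006, 0),
    el_us(0x0028, 0x0010, nr),
    el_us(0x0028, 0x0011, nc),
    el_ds(0x0028, 0x0030, image$pixel_spacing),
    el_us(0x0028, 0x0100, 8),
    el_us(0x0028, 0x0101, 8),
    el_us(0x0028, 0x0102, 7),
    el_us(0x0028, 0x0103, 0),
    el_raw(0x7FE0, 0x0010, "OB", as.raw(inter))
  )
  dcm_write_file(path, SOP_SC, elements)
}

#' Read back a secondary-capture overlay as an RGB array
#'
#' @param path Path to an RGB secondary-capture DICOM written by
#'   \code{\link{write_secondary_capture}}.
#' @return A rows x cols x 3 integer array of 8-bit channel values.
#' @export
read_secondary_capture <- function(path) {
  ds <- dcm_read_file(path)
  arr <- decode_pixels(ds)
  if (length(dim(arr)) != 3) stop("not an RGB secondary-capture file")
  arr
}

#' Write quantification results to CSV
#'
#' One row per result with areas in cm^2, rounded to two decimals.
#'
#' @param results A list of \code{\link{quant_result}} objects.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_results <- function(results, path) {
  df <- results_to_df(results)
  for (col in c("outer_cm2", "inner_cm2", "sat_cm2", "vat_cm2"))
    df[[col]] <- round(df[[col]], 2)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

results_to_df <- function(results) {
  if (length(results) == 0)
    return(data.frame(source_id = character(), modality = character(),
                      outer_cm2 = numeric(), inner_cm2 = numeric(),
                      sat_cm2 = numeric(), vat_cm2 = numeric()))
  do.call(rbind, lapply(results, function(r) data.frame(
    source_id = r$source_id, modality = r$modality,
    outer_cm2 = r$outer_area_cm2, inner_cm2 = r$inner_area_cm2,
    sat_cm2 = r$sat_area_cm2, vat_cm2 = r$vat_area_cm2,
    stringsAsFactors = FALSE)))
}

#' Read a results CSV back into quant_result objects
#'
#' @param path CSV written by \code{\link{write_results}}.
#' @return A list of \code{\link{quant_result}} objects.
#' @export
read_results <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(seq_len(nrow(df)), function(i) quant_result(
    df$outer_cm2[i], df$inner_cm2[i], df$sat_cm2[i], df$vat_cm2[i],
    modality = df$modality[i], source_id = df$source_id[i],
    boundary_tol_cm2 = Inf))
}

#' Write one result as JSON
#'
#' Mirrors the CSV fields plus a digest of the parameters used, for
#' machine-readable per-slice output.
#'
#' @param result A \code{\link{quant_result}}.
#' @param path Output path.
#' @param params_digest Optional digest string identifying the configuration.
#' @return The path, invisibly.
#' @export
write_result_json <- function(result, path, params_digest = "") {
  jsonlite::write_json(list(
    source_id = result$source_id, modality = result$modality,
    outer_cm2 = result$outer_area_cm2, inner_cm2 = result$inner_area_cm2,
    sat_cm2 = result$sat_area_cm2, vat_cm2 = result$vat_area_cm2,
    params_digest = params_digest), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
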