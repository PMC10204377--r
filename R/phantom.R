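# Parametric paired CT/MR abdominal phantom: nested ellipses (subcutaneous
# fat ring, muscle wall, visceral cavity) with elliptical visceral fat
# blobs, an optional vertebral-ring confounder with a fat islet in the
# spinal canal, optional bowel gas, per-modality Gaussian noise, and a
# smooth multiplicative MR bias field. Ground truth is derived from the
# noiseless geometry, so recovery can be asserted exactly.

#' Specify a synthetic abdominal phantom
#'
#' Geometry is given in millimetres on a pixel grid; the same specification
#' renders pixel-identical geometry for CT and MR (only the intensity
#' mapping, the noise realisation and the MR bias field differ).
#'
#' @param grid \code{c(rows, cols)} pixel grid, default 256 x 256.
#' @param pixel_spacing \code{c(row_mm, col_mm)}, default 1.75 mm isotropic
#'   (a 448 mm abdominal field of view).
#' @param body_radii \code{c(a_mm, b_mm)} ellipse semi-axes of the body
#'   cross-section (a = left-right, b = anterior-posterior).
#' @param sat_thickness_mm Subcutaneous fat ring thickness, >= 0.
#' @param muscle_thickness_mm Abdominal-wall muscle thickness, > 0.
#' @param visceral_blobs List of visceral fat blobs, each
#'   \code{c(u, v, r1_mm, r2_mm, angle_deg)} where (u, v) are the centre as
#'   fractions (-1..1) of the cavity semi-axes and r1/r2 the blob semi-axes.
#' @param spine_confounder Render a posterior vertebral ring (bone) with a
#'   small fat islet inside the spinal canal.
#' @param bowel_gas Render an air pocket inside the cavity.
#' @param tissue_values Named list mapping tissue to \code{c(HU, MR a.u.)}.
#'   Defaults: fat (-100, 1000), muscle (50, 150), organ (40, 120),
#'   air (-1000, 0), bone (700, 30).
#' @param noise_sd \code{c(ct, mr)} additive Gaussian noise SDs: 10 HU for
#'   CT and 3 percent of the fat intensity for MR.
#' @param mr_bias_amplitude Amplitude A of the multiplicative field
#'   \code{1 + A sin(pi u) cos(pi v)} (range 1-A .. 1+A), in [0, 0.5).
#' @param seed Integer seed controlling the noise realisations.
#' @return An object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(grid = c(256, 256), pixel_spacing = c(1.75, 1.75),
                         body_radii = c(160, 120), sat_thickness_mm = 25,
                         muscle_thickness_mm = 12,
                         visceral_blobs = list(c(-0.45, -0.2, 22, 16, 20),
                                               c(0.4, -0.35, 18, 14, -35),
                                               c(0.1, 0.35, 20, 13, 70),
                                               c(-0.15, -0.55, 15, 12, 0)),
                         spine_confounder = TRUE, bowel_gas = FALSE,
                         tissue_values = NULL,
                         noise_sd = c(ct = 10, mr = 30),
                         mr_bias_amplitude = 0.2, seed = 1L) {
  defaults <- list(fat = c(-100, 1000), muscle = c(50, 150),
                   organ = c(40, 120), air = c(-1000, 0), bone = c(700, 30))
  if (is.null(tissue_values)) tissue_values <- defaults
  else tissue_values <- utils::modifyList(defaults, tissue_values)
  cavity <- body_radii - sat_thickness_mm - muscle_thickness_mm
  if (sat_thickness_mm < 0 || muscle_thickness_mm <= 0)
    stop("layer thicknesses must be positive (SAT may be zero)")
  if (any(cavity <= 5))
    stop("geometrically impossible spec: visceral cavity is empty")
  if (mr_bias_amplitude < 0 || mr_bias_amplitude >= 0.5)
    stop("mr_bias_amplitude must be in [0, 0.5)")
  half_fov <- grid / 2 * pixel_spacing
  if (any(body_radii + 4 * pixel_spacing > half_fov))
    stop("body does not fit in the field of view")
  structure(list(grid = as.integer(grid), pixel_spacing = pixel_spacing,
                 body_radii = body_radii, sat_thickness_mm = sat_thickness_mm,
                 muscle_thickness_mm = muscle_thickness_mm,
                 visceral_blobs = visceral_blobs,
                 spine_confounder = isTRUE(spine_confounder),
                 bowel_gas = isTRUE(bowel_gas),
                 tissue_values = tissue_values, noise_sd = noise_sd,
                 mr_bias_amplitude = mr_bias_amplitude,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Label codes for the rendered geometry.
LBL <- c(air = 0, sat = 1, muscle = 2, organ = 3, vat = 4, bone = 5,
         conf_fat = 6, bowel = 7)

render_labels <- function(spec) {
  nr <- spec$grid[1]; nc <- spec$grid[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  y <- (matrix(rep(seq_len(nr), nc), nr) - cy) * spec$pixel_spacing[1]
  x <- (matrix(rep(seq_len(nc), each = nr), nr) - cx) * spec$pixel_spacing[2]
  a <- spec$body_radii[1]; b <- spec$body_radii[2]
  ts <- spec$sat_thickness_mm; tm <- spec$muscle_thickness_mm
  inside <- function(ax, bx, x0 = 0, y0 = 0, ang = 0) {
    if (ang != 0) {
      th <- ang * pi / 180
      xr <- (x - x0) * cos(th) + (y - y0) * sin(th)
      yr <- -(x - x0) * sin(th) + (y - y0) * cos(th)
    } else { xr <- x - x0; yr <- y - y0 }
    (xr / ax)^2 + (yr / bx)^2 <= 1
  }
  lab <- matrix(LBL["air"], nr, nc)
  lab[inside(a, b)] <- LBL["sat"]
  in_muscle_outer <- inside(a - ts, b - ts)
  lab[in_muscle_outer] <- LBL["muscle"]
  cav <- c(a - ts - tm, b - ts - tm)
  in_cavity <- inside(cav[1], cav[2])
  lab[in_cavity] <- LBL["organ"]
  for (blob in spec$visceral_blobs) {
    bl <- inside(blob[3], blob[4], blob[1] * cav[1], blob[2] * cav[2],
                 blob[5]) & in_cavity
    lab[bl] <- LBL["vat"]
  }
  if (spec$bowel_gas) {
    gas <- inside(14, 11, -0.35 * cav[1], 0.3 * cav[2]) & in_cavity
    lab[gas] <- LBL["bowel"]
  }
  if (spec$spine_confounder) {
    ys <- 0.55 * cav[2]
    d2 <- x^2 + (y - ys)^2
    ring <- d2 <= 14^2 & d2 > 6^2 & in_cavity
    canal <- d2 <= 6^2 & in_cavity
    islet <- d2 <= 2.5^2 & in_cavity
    lab[ring] <- LBL["bone"]
    lab[canal] <- LBL["organ"]
    lab[islet] <- LBL["conf_fat"]
  }
  lab
}

phantom_truth <- function(spec, lab) {
  paw <- spec$pixel_spacing[1] * spec$pixel_spacing[2] / 100
  a <- spec$body_radii[1]; b <- spec$body_radii[2]
  nr <- spec$grid[1]; nc <- spec$grid[2]
  cy <- (nr + 1) / 2; cx <- (nc + 1) / 2
  y <- (matrix(rep(seq_len(nr), nc), nr) - cy) * spec$pixel_spacing[1]
  x <- (matrix(rep(seq_len(nc), each = nr), nr) - cx) * spec$pixel_spacing[2]
  ts <- spec$sat_thickness_mm
  inner_mask <- (x / (a - ts))^2 + (y / (b - ts))^2 <= 1
  body <- lab != LBL["air"]
  structure(list(
    sat_mask = lab == LBL["sat"],
    vat_mask = lab == LBL["vat"],
    body_mask = body,
    inner_mask = inner_mask,
    muscle_mask = lab == LBL["muscle"],
    organ_mask = lab == LBL["organ"] | lab == LBL["bone"] |
                 lab == LBL["bowel"],
    confounder_mask = lab == LBL["conf_fat"],
    sat_area_cm2 = sum(lab == LBL["sat"]) * paw,
    vat_area_cm2 = sum(lab == LBL["vat"]) * paw,
    outer_area_cm2 = sum(body) * paw,
    inner_area_cm2 = sum(inner_mask) * paw
  ), class = "phantom_truth")
}

# Smooth multiplicative bias field 1 + A sin(pi u) cos(pi v),
# u, v in [-1/2, 1/2] across the grid.
phantom_bias_field <- function(spec) {
  nr <- spec$grid[1]; nc <- spec$grid[2]
  v <- (seq_len(nr) - (nr + 1) / 2) / nr
  u <- (seq_len(nc) - (nc + 1) / 2) / nc
  1 + spec$mr_bias_amplitude * outer(cos(pi * v), sin(pi * u))
}

#' Render a phantom as a CT or MR image with ground truth
#'
#' @param spec A \code{\link{phantom_spec}}.
#' @param modality \code{"CT"} or \code{"MR"}.
#' @return A list with \code{image} (an \code{\link{abdominal_image}}) and
#'   \code{truth} (a \code{phantom_truth} with exact masks and areas). The
#'   truth is identical for both modalities of the same spec.
#' @export
generate_phantom <- function(spec, modality = c("CT", "MR")) {
  modality <- match.arg(toupper(modality), c("CT", "MR"))
  lab <- render_labels(spec)
  tv <- spec$tissue_values
  chan <- if (modality == "CT") 1 else 2
  value_of <- c(tv$air[chan], tv$fat[chan], tv$muscle[chan], tv$organ[chan],
                tv$fat[chan], tv$bone[chan], tv$fat[chan], tv$air[chan])
  px <- matrix(value_of[lab + 1], spec$grid[1], spec$grid[2])
  if (modality == "MR" && spec$mr_bias_amplitude > 0)
    px <- px * phantom_bias_field(spec)
  seed_off <- if (modality == "CT") 1L else 2L
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
         else NULL
  set.seed((spec$seed + seed_off) %% 2147483647L)
  sd <- unname(spec$noise_sd[if (modality == "CT") 1 else 2])
  px <- px + matrix(stats::rnorm(length(px), sd = sd), nrow(px))
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  if (modality == "MR") px[px < 0] <- 0
  image <- abdominal_image(px, modality, spec$pixel_spacing,
                           source_id = sprintf("phantom-%d", spec$seed),
                           bias_corrected = modality == "CT" ||
                             spec$mr_bias_amplitude == 0)
  list(image = image, truth = phantom_truth(spec, lab))
}

#' Default cohort parameter ranges
#'
#' Body sizes span outer areas of roughly 420-980 cm^2, the spread reported
#' for adult abdominal cross-sections, so agreement statistics are exercised
#' over a realistic range.
#'
#' @return Named list of ranges used by \code{\link{generate_cohort}}.
#' @export
cohort_ranges <- function() {
  list(outer_area_cm2 = c(420, 980), aspect = c(1.15, 1.4),
       sat_thickness_mm = c(12, 40), muscle_thickness_mm = c(8, 15),
       n_blobs = c(3, 6), blob_r_mm = c(10, 26),
       mr_bias_amplitude = c(0.1, 0.3), bowel_gas_prob = 0.4,
       spine_confounder_prob = 1.0)
}

#' Generate a seeded cohort of paired CT/MR phantoms
#'
#' @param n Number of phantoms (>= 1).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @param ranges Parameter ranges, see \code{\link{cohort_ranges}}.
#' @return A list of \code{n} elements, each with \code{spec}, \code{ct},
#'   \code{mr} (abdominal images) and \code{truth}.
#' @export
generate_cohort <- function(n, seed = 1L, ranges = cohort_ranges()) {
  if (n < 1) stop("n must be >= 1")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
         else NULL
  set.seed(seed %% 2147483647L)
  runif2 <- function(r) stats::runif(1, r[1], r[2])
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    S <- runif2(ranges$outer_area_cm2) * 100  # mm^2
    ar <- runif2(ranges$aspect)
    a <- sqrt(S * ar / pi); b <- sqrt(S / (ar * pi))
    ts <- runif2(ranges$sat_thickness_mm)
    tm <- runif2(ranges$muscle_thickness_mm)
    cav <- c(a, b) - ts - tm
    nb <- sample(ranges$n_blobs[1]:ranges$n_blobs[2], 1)
    blobs <- lapply(seq_len(nb), function(k) {
      r1 <- runif2(ranges$blob_r_mm); r2 <- runif2(ranges$blob_r_mm)
      r1 <- min(r1, 0.45 * min(cav)); r2 <- min(r2, 0.45 * min(cav))
      c(stats::runif(1, -0.55, 0.55), stats::runif(1, -0.6, 0.45),
        r1, r2, stats::runif(1, -90, 90))
    })
    specs[[i]] <- phantom_spec(
      body_radii = c(a, b), sat_thickness_mm = ts, muscle_thickness_mm = tm,
      visceral_blobs = blobs,
      spine_confounder = stats::runif(1) < ranges$spine_confounder_prob,
      bowel_gas = stats::runif(1) < ranges$bowel_gas_prob,
      mr_bias_amplitude = runif2(ranges$mr_bias_amplitude),
      seed = ((seed %% 1000000L) * 1009L + i * 7919L) %% 2147483647L)
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  lapply(seq_len(n), function(i) {
    ct <- generate_phantom(specs[[i]], "CT")
    mr <- generate_phantom(specs[[i]], "MR")
    si <- sprintf("phantom-%02d", i)
    ct$image$source_id <- si; mr$image$source_id <- si
    list(spec = specs[[i]], ct = ct$image, mr = mr$image, truth = ct$truth)
  })
}

#' Serialise a phantom spec as JSON
#' @param spec A \code{\link{phantom_spec}}.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_phantom_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a phantom spec from JSON
#' @param path JSON path written by \code{\link{write_phantom_spec}}.
#' @return A \code{\link{phantom_spec}}.
#' @export
read_phantom_spec <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  blobs <- obj$visceral_blobs
  if (is.matrix(blobs)) blobs <- lapply(seq_len(nrow(blobs)),
                                        function(i) blobs[i, ])
  phantom_spec(grid = obj$grid, pixel_spacing = obj$pixel_spacing,
               body_radii = obj$body_radii,
               sat_thickness_mm = obj$sat_thickness_mm,
               muscle_thickness_mm = obj$muscle_thickness_mm,
               visceral_blobs = blobs,
               spine_confounder = obj$spine_confounder,
               bowel_gas = obj$bowel_gas,
               tissue_values = obj$tissue_values,
               noise_sd = unlist(obj$noise_sd),
               mr_bias_amplitude = obj$mr_bias_amplitude, seed = obj$seed)
}
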