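# Active-contour (snake) boundary detection. A closed spline of n points
# minimises Kass-style internal energy (tension alpha |v'|^2 + rigidity
# beta |v''|^2) plus an external image energy, with a balloon pressure term
# so the contour keeps moving through flat image regions. The internal
# energy is handled semi-implicitly (cyclic pentadiagonal system solved once
# up front), the external and balloon forces explicitly.

#' Snake solver parameters
#'
#' @param alpha Tension weight (first-derivative penalty), >= 0.
#' @param beta Rigidity weight (second-derivative penalty), >= 0.
#' @param gamma Time step; the per-iteration displacement from external
#'   forces is bounded by \code{gamma} times the force magnitude.
#' @param balloon Pressure weight along the inward normal; negative values
#'   shrink the contour, which is how both pipeline stages are driven.
#' @param max_iter Iteration cap, >= 1.
#' @param tol Convergence threshold on mean point displacement, pixels.
#' @param n_points Number of contour points, resampled to uniform arc length
#'   every iteration.
#' @param edge_weight Multiplier on the edge-map gradient force; the snake
#'   comes to rest where this force balances the balloon pressure.
#' @param refine_iter After the balloon-driven phase converges, this many
#'   additional iterations run with the balloon switched off so the contour
#'   relaxes from its pressure-offset position onto the edge crest itself.
#' @return An object of class \code{snake_params}.
#' @export
snake_params <- function(alpha = 0.05, beta = 0.5, gamma = 1.0,
                         balloon = -0.3, max_iter = 500, tol = 0.05,
                         n_points = 200, edge_weight = 2, refine_iter = 60) {
  if (alpha < 0 || beta < 0) stop("alpha and beta must be >= 0")
  if (gamma <= 0) stop("gamma must be > 0")
  if (max_iter < 1) stop("max_iter must be >= 1")
  if (tol <= 0) stop("tol must be > 0")
  if (n_points < 16) stop("n_points must be >= 16")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, balloon = balloon,
                 max_iter = max_iter, tol = tol, n_points = n_points,
                 edge_weight = edge_weight, refine_iter = refine_iter),
            class = "snake_params")
}

# Inverse of (I + gamma * A) for the cyclic internal-energy matrix.
snake_system_inverse <- function(n, alpha, beta, gamma) {
  circ <- function(offsets, values) {
    m <- matrix(0, n, n)
    for (k in seq_along(offsets)) {
      idx <- ((seq_len(n) - 1 + offsets[k]) %% n) + 1
      m[cbind(seq_len(n), idx)] <- m[cbind(seq_len(n), idx)] + values[k]
    }
    m
  }
  d2 <- circ(c(-1, 0, 1), c(-1, 2, -1))
  d4 <- circ(c(-2, -1, 0, 1, 2), c(1, -4, 6, -4, 1))
  solve(diag(n) + gamma * (alpha * d2 + beta * d4))
}

# Bilinear interpolation of img at real-valued (row, col) positions.
interp_bilinear <- function(img, r, c) {
  nr <- nrow(img); nc <- ncol(img)
  r <- pmin(pmax(r, 1), nr); c <- pmin(pmax(c, 1), nc)
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(c), nc - 1)
  fr <- r - r0; fc <- c - c0
  img[cbind(r0, c0)] * (1 - fr) * (1 - fc) +
    img[cbind(r0 + 1, c0)] * fr * (1 - fc) +
    img[cbind(r0, c0 + 1)] * (1 - fr) * fc +
    img[cbind(r0 + 1, c0 + 1)] * fr * fc
}

# Central-difference gradient of a 2-D grid.
grid_gradient <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  gr <- (img[c(2:nr, nr), ] - img[c(1, 1:(nr - 1)), ]) / 2
  gc <- (img[, c(2:nc, nc)] - img[, c(1, 1:(nc - 1))]) / 2
  list(dr = gr, dc = gc)
}

# Gaussian-smoothed gradient-magnitude edge map, normalised to peak 1.
edge_map_from <- function(img, sigma = 2) {
  sm <- as.matrix(EBImage::gblur(img, sigma = sigma))
  g <- grid_gradient(sm)
  e <- sqrt(g$dr^2 + g$dc^2)
  m <- max(e)
  if (m > 0) e / m else e
}

#' Evolve a snake on an edge map
#'
#' Iterates the semi-implicit Kass update until the mean point displacement
#' falls below \code{params$tol} or \code{params$max_iter} is reached. The
#' contour is resampled to uniform arc-length spacing every iteration. The
#' solver contains no randomness: identical inputs give identical output.
#'
#' @param init Initial \code{\link{contour}}.
#' @param edge_map Non-negative 2-D grid whose ridges attract the snake
#'   (typically \code{edge_map_from} of a mask or fat-likelihood image).
#' @param params A \code{\link{snake_params}} object.
#' @param min_area_px2 Collapse guard: evolution stops with an error if the
#'   enclosed area falls below this (px^2).
#' @return The converged \code{\link{contour}}.
#' @export
evolve_snake <- function(init, edge_map, params = snake_params(),
                         min_area_px2 = 25) {
  if (!inherits(init, "contour")) stop("init must be a contour")
  if (!is.matrix(edge_map)) stop("edge_map must be a matrix")
  n <- params$n_points
  pts <- resample_points(init$points, n)
  minv <- snake_system_inverse(n, params$alpha, params$beta, params$gamma)
  grad <- grid_gradient(edge_map)
  nr <- nrow(edge_map); nc <- ncol(edge_map)
  step <- function(pts, balloon) {
    # inward unit normals from the central-difference tangent
    nxt <- rbind(pts[-1, , drop = FALSE], pts[1, , drop = FALSE])
    prv <- rbind(pts[n, , drop = FALSE], pts[-n, , drop = FALSE])
    tang <- nxt - prv
    tlen <- pmax(sqrt(rowSums(tang^2)), 1e-12)
    nrml <- cbind(-tang[, 2], tang[, 1]) / tlen
    centroid <- colMeans(pts)
    if (sum((centroid[1] - pts[, 1]) * nrml[, 1] +
            (centroid[2] - pts[, 2]) * nrml[, 2]) < 0) nrml <- -nrml
    f_edge <- cbind(interp_bilinear(grad$dr, pts[, 1], pts[, 2]),
                    interp_bilinear(grad$dc, pts[, 1], pts[, 2]))
    force <- params$edge_weight * f_edge - balloon * nrml
    new_pts <- minv %*% (pts + params$gamma * force)
    new_pts[, 1] <- pmin(pmax(new_pts[, 1], 1), nr)
    new_pts[, 2] <- pmin(pmax(new_pts[, 2], 1), nc)
    new_pts
  }
  run_phase <- function(pts, balloon, iters) {
    for (iter in seq_len(iters)) {
      new_pts <- step(pts, balloon)
      # max (not mean) displacement: a short arc still sliding into a
      # concavity must keep the whole contour iterating
      disp <- max(sqrt(rowSums((new_pts - pts)^2)))
      pts <- resample_area_preserving(new_pts, n)
      if (abs(polygon_signed_area(pts)) < min_area_px2)
        stop("snake collapsed below the minimum enclosed area")
      if (disp < params$tol) break
    }
    pts
  }
  pts <- run_phase(pts, params$balloon, params$max_iter)
  if (params$refine_iter > 0 && params$balloon != 0)
    pts <- run_phase(pts, 0, params$refine_iter)
  contour(pts, check_simple = FALSE)
}

# Uniform arc-length resampling replaces arcs by chords and therefore
# shrinks the enclosed area by ~r (1 - cos(pi/n)) every call; over hundreds
# of iterations that bias would drag a balanced snake off its edge. Rescale
# about the centroid so the enclosed area is exactly preserved.
resample_area_preserving <- function(points, n) {
  res <- resample_points(points, n)
  a_pre <- abs(polygon_signed_area(points))
  a_post <- abs(polygon_signed_area(res))
  if (a_post > 1e-9 && a_pre > 1e-9) {
    ctr <- contour_centroid(res)
    res <- sweep(sweep(res, 2, ctr) * sqrt(a_pre / a_post), 2, ctr, "+")
  }
  res
}

# Convex hull of a mask's foreground, expanded radially by expand_px.
mask_convex_hull <- function(mask, expand_px = 2, n_points = 200) {
  idx <- which(mask != 0, arr.ind = TRUE)
  if (nrow(idx) < 3) stop("mask has too few foreground pixels for a hull")
  h <- grDevices::chull(idx[, 2], idx[, 1])
  pts <- idx[h, c(1, 2), drop = FALSE]
  ctr <- colMeans(pts)
  vec <- sweep(pts, 2, ctr)
  len <- pmax(sqrt(rowSums(vec^2)), 1e-9)
  pts <- pts + expand_px * vec / len
  contour(resample_points(pts[, 1:2, drop = FALSE], n_points),
          check_simple = FALSE)
}

#' Detect the outer (skin) contour
#'
#' Initialises the snake at the convex hull of the body mask (dilated by two
#' pixels) and lets a gentle inward balloon settle it onto the mask boundary;
#' the edge map is the gradient magnitude of the smoothed mask, which makes
#' the stage identical for CT and MR.
#'
#' @param image The \code{\link{abdominal_image}} (carried for interface
#'   symmetry; the attraction comes from the mask).
#' @param body A \code{body_mask} from \code{\link{compute_body_mask}}.
#' @param params A \code{\link{snake_params}}; default balloon -0.3.
#' @return The outer \code{\link{contour}}.
#' @export
detect_outer_contour <- function(image, body,
                                 params = snake_params(balloon = -0.3)) {
  mask <- body$mask * 1
  init <- mask_convex_hull(mask, expand_px = 2, n_points = params$n_points)
  evolve_snake(init, edge_map_from(mask, sigma = 2), params)
}

#' Detect the inner abdominal-wall contour
#'
#' Starts from the outer contour scaled slightly toward its centroid and
#' shrinks under balloon pressure until it locks onto the inner edge of the
#' subcutaneous fat ring. The attraction field is the gradient of a
#' fat-likelihood indicator (classified fat or outside-body, versus
#' muscle/organ), so on both modalities the snake rests at the fat/muscle
#' transition; in a subject with no subcutaneous fat the skin edge itself
#' stops the contour just inside the outer one.
#'
#' @param image The \code{\link{abdominal_image}}.
#' @param outer The detected outer \code{\link{contour}}.
#' @param params A \code{\link{snake_params}}; default balloon -0.5.
#' @param body Optional precomputed \code{body_mask} (recomputed if missing).
#' @param fat Optional precomputed fat classification grid (recomputed from
#'   the modality's default threshold if missing).
#' @param start_scale Initial shrink factor applied to the outer contour.
#' @return The inner \code{\link{contour}}, strictly inside \code{outer}.
#' @export
detect_inner_contour <- function(image, outer,
                                 params = snake_params(balloon = -0.5),
                                 body = NULL, fat = NULL,
                                 start_scale = 0.98) {
  stop_if_not_image(image)
  if (is.null(body)) body <- compute_body_mask(image)
  if (is.null(fat))
    fat <- classify_fat(image, default_threshold_spec(image$modality), body)
  likelihood <- ((fat != 0) | (body$mask == 0)) * 1
  emap <- edge_map_from(likelihood, sigma = 2)
  ctr <- contour_centroid(outer$points)
  init_pts <- sweep(sweep(outer$points, 2, ctr) * start_scale, 2, ctr, "+")
  inner <- evolve_snake(contour(init_pts, check_simple = FALSE), emap, params)
  inner <- clamp_inside(inner, outer)
  if (contour_area(inner) >= contour_area(outer))
    stop("inner contour area is not smaller than the outer contour area")
  inner
}

# Pull any points that drifted outside the enclosing polygon back toward the
# centroid until containment holds (discretisation guard for degenerate
# cases where the two contours nearly coincide).
clamp_inside <- function(inner, outer, max_pass = 60) {
  pts <- inner$points
  ctr <- contour_centroid(outer$points)
  for (pass in seq_len(max_pass)) {
    out <- !points_in_polygon(pts[, 1], pts[, 2], outer$points)
    if (!any(out)) break
    pts[out, ] <- sweep(sweep(pts[out, , drop = FALSE], 2, ctr) * 0.99,
                        2, ctr, "+")
  }
  contour(pts, check_simple = FALSE)
}
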