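# Cross-modality agreement statistics: Pearson correlation, Bland-Altman
# bias and limits of agreement (bias +/- 1.96 SD of the paired differences,
# sample SD with n-1 denominator), Lilliefors-type Kolmogorov-Smirnov
# normality per variable, and a paired two-tailed t-test. The sign
# convention is MR minus CT: bias = mean(y - x) with x the CT values.

#' Compare paired CT and MR measurements
#'
#' @param x Numeric vector of CT-derived values.
#' @param y Numeric vector of MR-derived values, paired with \code{x}.
#' @return An object of class \code{agreement_result} with fields
#'   \code{pearson_r}, \code{bias} (mean of y - x), \code{loa_low},
#'   \code{loa_high} (bias -/+ 1.96 SD of differences),
#'   \code{loa_ci_halfwidth} (95 percent CI half-width of the limits),
#'   \code{t_statistic}, \code{t_pvalue}, \code{ks_pvalue_x},
#'   \code{ks_pvalue_y}, \code{n}.
#' @details Degenerate cases: when the differences have zero variance the
#'   limits collapse onto the bias and the t-test p-value is 1 for zero bias
#'   (0 otherwise) by convention; when either input has zero variance the
#'   correlation is undefined and returned as \code{NA} with a warning,
#'   while the bias remains defined. The KS normality p-values use the
#'   Lilliefors correction (parameters estimated from the sample) and are
#'   \code{NA} for n < 5 or zero-variance vectors.
#' @export
compare_modalities <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    stop("x and y must have equal length (paired values)")
  n <- length(x)
  if (n < 3) stop("at least 3 pairs are required")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("inputs must be finite")
  d <- y - x
  bias <- mean(d)
  sd_d <- stats::sd(d)
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance input: Pearson correlation undefined")
    NA_real_
  } else stats::cor(x, y)
  if (sd_d == 0) {
    t_stat <- if (bias == 0) 0 else sign(bias) * Inf
    t_p <- if (bias == 0) 1 else 0
  } else {
    tt <- stats::t.test(y, x, paired = TRUE)
    t_stat <- unname(tt$statistic)
    t_p <- tt$p.value
  }
  lillie_p <- function(v) {
    if (length(v) < 5 || stats::sd(v) == 0) return(NA_real_)
    tryCatch(nortest::lillie.test(v)$p.value, error = function(e) NA_real_)
  }
  structure(list(
    pearson_r = r,
    bias = bias,
    loa_low = bias - 1.96 * sd_d,
    loa_high = bias + 1.96 * sd_d,
    loa_ci_halfwidth = stats::qt(0.975, n - 1) * sd_d * sqrt(3 / n),
    t_statistic = t_stat,
    t_pvalue = t_p,
    ks_pvalue_x = lillie_p(x),
    ks_pvalue_y = lillie_p(y),
    n = n
  ), class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement> n=%d  r=%.4f  bias=%.3f  LOA [%.3f, %.3f]  t p=%.3g\n",
    x$n, x$pearson_r, x$bias, x$loa_low, x$loa_high, x$t_pvalue))
  invisible(x)
}

agreement_measures <- c("outer", "inner", "sat", "vat")

measure_field <- function(m) paste0(m, "_area_cm2")

#' Cross-modality agreement report
#'
#' Pairs CT and MR results by \code{source_id}, computes
#' \code{\link{compare_modalities}} for each measure (outer, inner, SAT,
#' VAT), writes a CSV of the agreement rows and, per measure, a scatter plot
#' and a Bland-Altman plot.
#'
#' @param results_ct,results_mr Lists of \code{\link{quant_result}} objects.
#' @param out_dir Output directory (created if needed).
#' @param plot_format \code{"png"} or \code{"pdf"}.
#' @return Invisibly, a data frame with one row per measure.
#' @export
agreement_report <- function(results_ct, results_mr, out_dir,
                             plot_format = c("png", "pdf")) {
  plot_format <- match.arg(plot_format)
  ids_ct <- vapply(results_ct, function(r) r$source_id, "")
  ids_mr <- vapply(results_mr, function(r) r$source_id, "")
  common <- intersect(ids_ct, ids_mr)
  unmatched <- c(setdiff(ids_ct, ids_mr), setdiff(ids_mr, ids_ct))
  if (length(unmatched) > 0)
    stop("unmatched source ids: ", paste(unmatched, collapse = ", "))
  if (length(common) == 0) stop("no paired results to compare")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ct_by <- results_ct[match(common, ids_ct)]
  mr_by <- results_mr[match(common, ids_mr)]
  rows <- lapply(agreement_measures, function(m) {
    f <- measure_field(m)
    x <- vapply(ct_by, function(r) r[[f]], 0)
    y <- vapply(mr_by, function(r) r[[f]], 0)
    agr <- compare_modalities(x, y)
    plot_agreement(x, y, agr, m, out_dir, plot_format)
    data.frame(measure = m, n = agr$n, pearson_r = agr$pearson_r,
               bias_cm2 = agr$bias, loa_low_cm2 = agr$loa_low,
               loa_high_cm2 = agr$loa_high,
               loa_ci_halfwidth_cm2 = agr$loa_ci_halfwidth,
               t_statistic = agr$t_statistic, t_pvalue = agr$t_pvalue,
               ks_pvalue_ct = agr$ks_pvalue_x, ks_pvalue_mr = agr$ks_pvalue_y,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.csv(df, file.path(out_dir, "agreement.csv"), row.names = FALSE)
  invisible(df)
}

plot_agreement <- function(x, y, agr, measure, out_dir, fmt) {
  open_dev <- function(name) {
    path <- file.path(out_dir, paste0(name, ".", fmt))
    if (fmt == "png") grDevices::png(path, width = 640, height = 640)
    else grDevices::pdf(path, width = 6, height = 6)
  }
  label <- toupper(measure)
  open_dev(paste0("scatter_", measure))
  lim <- range(c(x, y))
  graphics::plot(x, y, xlim = lim, ylim = lim, pch = 19, col = "steelblue",
                 xlab = sprintf("CT %s area (cm^2)", label),
                 ylab = sprintf("MR %s area (cm^2)", label),
                 main = sprintf("%s: CT vs MR (r = %.3f)", label,
                                agr$pearson_r))
  graphics::abline(0, 1, lty = 2)
  grDevices::dev.off()
  open_dev(paste0("bland_altman_", measure))
  means <- (x + y) / 2
  diffs <- y - x
  ylim <- range(c(diffs, agr$loa_low, agr$loa_high))
  graphics::plot(means, diffs, pch = 19, col = "firebrick", ylim = ylim,
                 xlab = sprintf("Mean of CT and MR %s (cm^2)", label),
                 ylab = "MR - CT (cm^2)",
                 main = sprintf("%s Bland-Altman (bias = %.2f cm^2)", label,
                                agr$bias))
  graphics::abline(h = agr$bias, col = "firebrick")
  graphics::abline(h = c(agr$loa_low, agr$loa_high), lty = 2)
  grDevices::dev.off()
}
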