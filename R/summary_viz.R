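#' Region-level Bonferroni significance threshold
#'
#' Family-wise threshold `alpha / n_regions`. With LD-adaptive,
#' quasi-independent regions this is the genome-wide region-level
#' significance level (e.g. 0.05 over 89001 autosomal regions gives 5.62e-7).
#'
#' @param alpha Family-wise error level in (0,1).
#' @param n_regions Number of regions tested.
#' @return The per-region threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_regions) {
  stopifnot(alpha > 0, alpha < 1)
  if (length(n_regions) != 1L || is.na(n_regions) || n_regions < 1)
    stop("n_regions must be a positive integer")
  alpha / n_regions
}

#' Genomic inflation factor
#'
#' Converts p-values to 1-df chi-square quantiles and divides their median by
#' the null expectation of the median (0.4549364).
#'
#' @param p_values P-values in (0,1\].
#' @return Lambda, the inflation factor.
#' @export
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0L) stop("no p-values")
  stopifnot(all(p_values > 0), all(p_values <= 1))
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / 0.4549364
}

.open_device <- function(out, width = 9, height = 6) {
  if (grepl("\\.pdf$", out, ignore.case = TRUE))
    grDevices::pdf(out, width = width, height = height)
  else grDevices::png(out, width = width * 100, height = height * 100)
}

.neglog10 <- function(p, cap = 50) {
  x <- -log10(p)
  if (any(x > cap, na.rm = TRUE))
    warning("-log10(p) values clipped at ", cap)
  pmin(x, cap)
}

# accept a results data.frame or a path to a written region-level TSV
.as_results_df <- function(x) {
  if (is.character(x) && length(x) == 1L)
    utils::read.table(x, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  else as.data.frame(x)
}

#' Miami plot comparing two tests across regions
#'
#' Mirrored -log10(p) panels (first test up, second down) against genomic
#' position, with dashed significance-threshold lines.
#'
#' @param results_top,results_bottom Data frames (or region-file paths) with
#'   columns `chrom`, `start` and a p-value column named by `p_col_*`.
#' @param p_col_top,p_col_bottom P-value column names.
#' @param threshold_top,threshold_bottom Significance thresholds drawn as
#'   dashed lines.
#' @param out Output image path (`.png` or `.pdf`).
#' @return Invisibly, the output path.
#' @export
miami_plot <- function(results_top, results_bottom, p_col_top = "MLC_p",
                       p_col_bottom = "MINP_RAW",
                       threshold_top = 5e-7, threshold_bottom = 5e-8,
                       out = "miami.png") {
  top <- .as_results_df(results_top)
  bot <- .as_results_df(results_bottom)
  if (nrow(top) == 0L || nrow(bot) == 0L) stop("empty results")
  yt <- .neglog10(top[[p_col_top]])
  yb <- .neglog10(bot[[p_col_bottom]])
  ymax <- max(c(yt, yb, .neglog10(c(threshold_top, threshold_bottom))),
              na.rm = TRUE) * 1.05
  .open_device(out)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(4, 4, 2, 1))
  plot.new()
  plot.window(xlim = range(c(top$start, bot$start)), ylim = c(-ymax, ymax))
  graphics::points(top$start, yt, pch = 20, col = "steelblue4")
  graphics::points(bot$start, -yb, pch = 20, col = "darkorange3")
  graphics::abline(h = 0)
  graphics::abline(h = .neglog10(threshold_top), lty = 2)
  graphics::abline(h = -.neglog10(threshold_bottom), lty = 2)
  graphics::axis(1)
  at <- pretty(c(-ymax, ymax))
  graphics::axis(2, at = at, labels = abs(at))
  graphics::title(xlab = "position (bp)", ylab = "-log10(p)",
                  main = paste(p_col_top, "(top) vs", p_col_bottom, "(bottom)"))
  graphics::box()
  invisible(out)
}

#' QQ plot of region-level p-values with genomic inflation factor
#'
#' @param p_values P-values (or a region-file path plus `p_col`).
#' @param out Output image path.
#' @param p_col Column to use when `p_values` is a file path.
#' @return The inflation factor lambda, invisibly alongside the path, as a
#'   list.
#' @export
qq_plot <- function(p_values, out = "qq.png", p_col = "MLC_p") {
  if (is.character(p_values) && length(p_values) == 1L && file.exists(p_values))
    p_values <- .as_results_df(p_values)[[p_col]]
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0L) stop("no p-values")
  lambda <- genomic_inflation(p_values)
  n <- length(p_values)
  obs <- .neglog10(sort(p_values))
  exp_ <- -log10((seq_len(n) - 0.5) / n)
  .open_device(out, 6, 6)
  on.exit(grDevices::dev.off())
  plot(rev(exp_), rev(obs), pch = 20, xlab = "expected -log10(p)",
       ylab = "observed -log10(p)",
       main = sprintf("lambda = %.3f", lambda))
  graphics::abline(0, 1, lty = 2)
  invisible(list(out = out, lambda = lambda))
}

#' Locus plot of region-level results over a contiguous window
#'
#' Plots -log10(p) for one or more tests across a set of contiguous regions,
#' with alternating background shading marking region boundaries.
#'
#' @param results Region-level data.frame (or file path).
#' @param tests Character vector of p-value column names to draw.
#' @param threshold Dashed significance line.
#' @param out Output image path.
#' @return Invisibly, the output path.
#' @export
locus_plot <- function(results, tests = c("MLC_p", "WALD_p"),
                       threshold = 5e-7, out = "locus.png") {
  res <- .as_results_df(results)
  if (nrow(res) == 0L) stop("empty results")
  res <- res[order(res$start), , drop = FALSE]
  ys <- lapply(tests, function(tc) .neglog10(res[[tc]]))
  ymax <- max(c(unlist(ys), .neglog10(threshold)), na.rm = TRUE) * 1.1
  .open_device(out)
  on.exit(grDevices::dev.off())
  plot.new()
  plot.window(xlim = c(min(res$start), max(res$end)), ylim = c(0, ymax))
  for (i in seq_len(nrow(res)))
    graphics::rect(res$start[i], 0, res$end[i], ymax, border = NA,
                   col = if (i %% 2) "grey92" else "grey85")
  cols <- grDevices::hcl.colors(max(length(tests), 2), "Dark 3")
  mids <- (res$start + res$end) / 2
  for (k in seq_along(tests))
    graphics::points(mids, ys[[k]], pch = 19, col = cols[k], type = "b")
  graphics::abline(h = .neglog10(threshold), lty = 2)
  graphics::axis(1); graphics::axis(2)
  graphics::title(xlab = "position (bp)", ylab = "-log10(p)")
  graphics::legend("topright", legend = tests, col = cols[seq_along(tests)],
                   pch = 19, bty = "n")
  graphics::box()
  invisible(out)
}

#' Visualize within-region LD-bin structure
#'
#' Left panel: pairwise correlation heatmap with variants grouped by LD bin;
#' right panel: variant position against bin assignment, with pruned
#' variants greyed out.
#'
#' @param corr Correlation matrix of the analyzed variants.
#' @param bins `ld_bins` assignment for the analyzed variants.
#' @param positions Positions of the analyzed variants.
#' @param pruned_positions Positions of variants pruned before binning
#'   (drawn in grey; may be empty).
#' @param out Output image path.
#' @return Invisibly, the output path.
#' @export
bin_plot <- function(corr, bins, positions, pruned_positions = integer(),
                     out = "bins.png") {
  corr <- as.matrix(corr)
  m <- nrow(corr)
  if (m == 0L) stop("empty correlation matrix")
  ord <- order(bins$bin_of, seq_len(m))
  .open_device(out, 10, 5)
  on.exit(grDevices::dev.off())
  graphics::layout(matrix(1:2, 1, 2))
  graphics::par(mar = c(4, 4, 2, 1))
  graphics::image(seq_len(m), seq_len(m), corr[ord, rev(ord), drop = FALSE],
                  zlim = c(-1, 1), col = grDevices::hcl.colors(64, "Blue-Red 3"),
                  xlab = "variant (by bin)", ylab = "variant (by bin)",
                  main = "pairwise correlation")
  b_ord <- bins$bin_of[ord]
  edges <- which(diff(b_ord) != 0) + 0.5
  graphics::abline(v = edges, h = m + 1 - edges, col = "black", lwd = 0.5)
  plot.new()
  xs <- c(positions, pruned_positions)
  plot.window(xlim = range(xs), ylim = c(0, bins$n_bins + 1))
  if (length(pruned_positions))
    graphics::points(pruned_positions, rep(0, length(pruned_positions)),
                     pch = 4, col = "grey60")
  graphics::points(positions, bins$bin_of, pch = 19,
                   col = grDevices::hcl.colors(bins$n_bins + 1,
                                               "Dark 3")[bins$bin_of])
  graphics::axis(1)
  graphics::axis(2, at = 0:bins$n_bins,
                 labels = c("pruned", seq_len(bins$n_bins)))
  graphics::title(xlab = "position (bp)", ylab = "LD bin",
                  main = "bin assignment")
  graphics::box()
  invisible(out)
}
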