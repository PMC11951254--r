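# p-values in scientific notation with 6 significant digits; other reals
# with 6 significant digits; NA stays "NA"
.fmt_p <- function(p) ifelse(is.na(p), NA, sprintf("%.5e", p))
.fmt_num <- function(x)
  ifelse(is.na(x), NA, trimws(formatC(x, digits = 6, format = "g")))

.region_tests <- c("MLC", "LC", "WALD", "PC80", "SKAT", "SKATO",
                   "SIMPLEM", "GATES")

.region_id_order <- function(ids) {
  num <- suppressWarnings(as.numeric(ids))
  if (!anyNA(num)) order(num) else order(ids)
}

#' Write the per-region result files
#'
#' Writes four tab-separated files — `<prefix>.region.tsv` (one row per
#' region with all eight region-level tests), `<prefix>.bin.tsv` (MLC
#' bin-level tests), `<prefix>.variant.tsv` (variant metadata, bin
#' assignment, single/joint estimates and VIF) and `<prefix>.pruned.tsv`
#' (excluded variants with reasons) — plus, when present in `results`,
#' the optional `<prefix>.allsnps.tsv` (pre-pruning single-variant results)
#' and `<prefix>.covariates.tsv`. Rows are sorted by region id; p-values are
#' printed in scientific notation with 6 significant digits.
#'
#' @param results List with data.frames `region`, `bins`, `variants`,
#'   `pruned` and optionally `allsnps`, `covariates` (as assembled by
#'   [run_regscan()]).
#' @param prefix Output path prefix.
#' @return Invisibly, the named vector of written paths.
#' @export
write_outputs <- function(results, prefix) {
  if (is.null(results$region) || nrow(results$region) == 0L)
    stop("no region results to write")
  wr <- function(df, suffix, p_cols = character(), num_cols = character()) {
    df <- df[.region_id_order(df$region_id), , drop = FALSE]
    for (cn in intersect(p_cols, names(df))) df[[cn]] <- .fmt_p(df[[cn]])
    for (cn in intersect(num_cols, names(df))) df[[cn]] <- .fmt_num(df[[cn]])
    path <- paste0(prefix, ".", suffix, ".tsv")
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
    path
  }
  p_cols_region <- c(paste0(.region_tests, "_p"), "MINP_RAW", "ACAT_P")
  num_cols_region <- c(paste0(.region_tests, "_stat"),
                       paste0(.region_tests, "_df"))
  paths <- c(
    region = wr(results$region, "region", p_cols_region, num_cols_region),
    bin = wr(results$bins, "bin", "p", c("estimate", "se", "stat")),
    variant = wr(results$variants, "variant",
                 c("p_single", "p_joint"),
                 c("maf", "beta_single", "se_single", "beta_joint",
                   "se_joint", "vif")),
    pruned = wr(results$pruned, "pruned"))
  if (!is.null(results$allsnps))
    paths <- c(paths, allsnps = wr(results$allsnps, "allsnps", "p",
                                   c("beta", "se", "maf")))
  if (!is.null(results$covariates))
    paths <- c(paths, covariates = wr(results$covariates, "covariates", "p",
                                      c("beta", "se")))
  invisible(paths)
}
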