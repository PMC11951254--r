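#' Minor allele frequency and flip flag of a dosage vector
#'
#' The ALT-allele frequency is `mean(dosage)/2`; the minor allele frequency is
#' `min(f, 1 - f)` and the flip flag is `TRUE` when the ALT allele is the
#' major allele (`f > 0.5`), in which case downstream recoding replaces the
#' column by `2 - dosage`.
#'
#' @param dosages Numeric vector of dosages in \[0,2\].
#' @return List with `maf` and `flip`.
#' @examples
#' compute_maf(c(0, 1, 2, 1)) # maf 0.5, no flip
#' @export
compute_maf <- function(dosages) {
  if (length(dosages) == 0L) stop("empty dosage vector")
  if (any(dosages < 0 | dosages > 2)) stop("dosages outside [0,2]")
  f <- mean(dosages) / 2
  list(maf = min(f, 1 - f), flip = f > 0.5)
}

#' Filter variants on MAF and missingness and recode to minor-allele dosage
#'
#' Monomorphic columns are pruned with reason `MONOMORPHIC`; columns with
#' `maf < maf_min` with reason `MAF_BELOW_MIN` (the threshold is inclusive for
#' keeping: `maf >= maf_min` is kept); columns whose pre-imputation
#' missingness exceeds `miss_max` with reason `MISSINGNESS_ABOVE_MAX`.
#' Surviving columns are recoded so the counted allele is the minor allele,
#' and `maf` / `flipped_to_minor` are filled in the variant metadata.
#'
#' @param block A `genotype_block`.
#' @param maf_min Minimum minor allele frequency (default 0.01).
#' @param miss_max Maximum missing-genotype fraction (default 0.05).
#' @param region_id Region identifier used in the prune log.
#' @return List with the filtered, recoded `block` and a `prune_log`
#'   data.frame (`region_id`, `variant_id`, `reason`).
#' @export
filter_variants <- function(block, maf_min = 0.01, miss_max = 0.05,
                            region_id = NA_character_) {
  m <- ncol(block$dosage)
  log_rows <- list()
  keep <- logical(m)
  for (j in seq_len(m)) {
    vid <- block$variants$variant_id[j]
    mf <- compute_maf(block$dosage[, j])
    block$variants$maf[j] <- mf$maf
    if (length(block$missingness) >= j && !is.na(block$missingness[j]) &&
        block$missingness[j] > miss_max) {
      log_rows[[length(log_rows) + 1L]] <- c(vid, "MISSINGNESS_ABOVE_MAX")
    } else if (mf$maf == 0) {
      log_rows[[length(log_rows) + 1L]] <- c(vid, "MONOMORPHIC")
    } else if (mf$maf < maf_min) {
      log_rows[[length(log_rows) + 1L]] <- c(vid, "MAF_BELOW_MIN")
    } else {
      keep[j] <- TRUE
      if (mf$flip) {
        block$dosage[, j] <- 2 - block$dosage[, j]
        block$variants$flipped_to_minor[j] <- TRUE
      }
    }
  }
  prune_log <- if (length(log_rows)) {
    lr <- do.call(rbind, log_rows)
    data.frame(region_id = region_id, variant_id = lr[, 1], reason = lr[, 2],
               stringsAsFactors = FALSE)
  } else data.frame(region_id = character(), variant_id = character(),
                    reason = character(), stringsAsFactors = FALSE)
  block$dosage <- block$dosage[, keep, drop = FALSE]
  block$variants <- block$variants[keep, , drop = FALSE]
  rownames(block$variants) <- NULL
  block$missingness <- block$missingness[keep]
  list(block = block, prune_log = prune_log)
}

#' Pairwise Pearson correlation of the variant dosage columns
#'
#' @param block A `genotype_block` with at least one variant and no
#'   zero-variance columns (guaranteed after [filter_variants()]).
#' @return m x m symmetric correlation matrix with unit diagonal.
#' @export
pairwise_correlation <- function(block) {
  if (ncol(block$dosage) < 1L) stop("no variants in block")
  v <- apply(block$dosage, 2, stats::var)
  if (any(v == 0)) stop("zero-variance dosage column; run filter_variants first")
  r <- stats::cor(block$dosage)
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Greedy LD pruning of near-duplicate variants
#'
#' Scans variants in ascending position order (ties by variant id) and prunes
#' a variant when its squared correlation with any already-kept variant
#' exceeds `r2_prune`. Deterministic for a fixed input; idempotent.
#'
#' @param corr Correlation matrix from [pairwise_correlation()].
#' @param variants Variant metadata data.frame aligned with `corr`.
#' @param r2_prune Squared-correlation threshold in (0,1\] (default 0.98;
#'   prunes only near-duplicates so the LD-bin structure is preserved).
#' @param region_id Region identifier for the prune log.
#' @return List with integer `keep` (indices kept, original order) and
#'   `prune_log` rows with reason `LD_PRUNED`.
#' @export
ld_prune <- function(corr, variants, r2_prune = 0.98,
                     region_id = NA_character_) {
  stopifnot(r2_prune > 0, r2_prune <= 1)
  m <- nrow(corr)
  ord <- order(variants$pos, variants$variant_id)
  kept <- integer(0)
  pruned <- integer(0)
  for (j in ord) {
    if (length(kept) && any(corr[j, kept]^2 > r2_prune)) {
      pruned <- c(pruned, j)
    } else kept <- c(kept, j)
  }
  prune_log <- if (length(pruned))
    data.frame(region_id = region_id,
               variant_id = variants$variant_id[sort(pruned)],
               reason = "LD_PRUNED", stringsAsFactors = FALSE)
  else data.frame(region_id = character(), variant_id = character(),
                  reason = character(), stringsAsFactors = FALSE)
  list(keep = sort(kept), prune_log = prune_log)
}

#' Per-variant variance inflation factors
#'
#' `VIF_j` is the j-th diagonal element of the inverse of the variant
#' correlation matrix, i.e. `1/(1 - R2_j)` where `R2_j` is from regressing
#' variant j on the other variants. Reported as `NA` (with a warning) when
#' the correlation matrix is singular or when n <= m.
#'
#' @param block A filtered `genotype_block`.
#' @return Numeric vector of VIFs (>= 1 up to numerical tolerance).
#' @export
compute_vif <- function(block) {
  m <- ncol(block$dosage)
  if (m == 0L) return(numeric(0))
  if (m == 1L) return(1)
  if (nrow(block$dosage) <= m) {
    warning("n <= m; VIFs reported as NA")
    return(rep(NA_real_, m))
  }
  r <- pairwise_correlation(block)
  inv <- tryCatch(solve(r), error = function(e) NULL)
  if (is.null(inv)) {
    warning("singular correlation matrix; VIFs reported as NA")
    return(rep(NA_real_, m))
  }
  diag(inv)
}
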