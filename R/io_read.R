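#' Read a region-definition table
#'
#' Reads a whitespace- or tab-delimited table of genomic regions (for example
#' the output of an LD-based genome partitioning tool, or user-defined genes
#' or windows). The header must contain chromosome, start and end columns
#' (matched case-insensitively against `chr`/`chrom`/`chromosome`,
#' `start`/`reg_start`, `end`/`stop`/`reg_end`); an optional region-id column
#' (`region_id`/`id`/`region`) is used when present, otherwise ids are
#' assigned `1..K` in file order. Intervals are 1-based and closed.
#'
#' @param path Path to the region table.
#' @return A data.frame of class `region_def` with columns `region_id`,
#'   `chrom`, `start`, `end`, one row per region, in file order.
#' @examples
#' tf <- tempfile()
#' writeLines(c("chr start end", "chr19 45385759 45428234"), tf)
#' read_region_definitions(tf)
#' @export
read_region_definitions <- function(path) {
  if (!file.exists(path)) stop("region file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (nrow(tab) == 0L) stop("no regions in ", path)
  nm <- tolower(names(tab))
  pick <- function(cands, what) {
    i <- which(nm %in% cands)[1]
    if (is.na(i)) stop("region file lacks a ", what, " column")
    i
  }
  ic <- pick(c("chr", "chrom", "chromosome"), "chromosome")
  is <- pick(c("start", "reg_start", "begin"), "start")
  ie <- pick(c("end", "stop", "reg_end"), "end")
  ii <- which(nm %in% c("region_id", "id", "region", "regionid"))[1]
  region_id <- if (!is.na(ii)) as.character(tab[[ii]]) else as.character(seq_len(nrow(tab)))
  out <- data.frame(region_id = region_id,
                    chrom = as.character(tab[[ic]]),
                    start = as.integer(tab[[is]]),
                    end = as.integer(tab[[ie]]),
                    stringsAsFactors = FALSE)
  bad <- which(out$start > out$end)
  if (length(bad))
    stop("start > end in region row(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(out$region_id))
    stop("duplicated region_id in ", path)
  # overlap check is advisory: regions are consumed as given
  if (nrow(out) > 1L) {
    o <- order(out$chrom, out$start)
    s <- out[o, ]
    ov <- s$chrom[-1] == s$chrom[-nrow(s)] & s$start[-1] <= s$end[-nrow(s)]
    if (any(ov)) warning(sum(ov), " overlapping region pair(s) in ", path)
  }
  class(out) <- c("region_def", "data.frame")
  out
}

#' Read phenotype and covariates keyed by sample ID
#'
#' Reads a delimited table with a header and a sample-ID column (first column,
#' or any column named `IID`/`sample`/`sample_id`/`id`, matched
#' case-insensitively). Rows with missing phenotype or covariate values are
#' dropped with a message. A binary phenotype coded 1/2 is remapped to 0/1
#' with a warning.
#'
#' @param path Path to the table.
#' @param phenotype_name Name of the phenotype column.
#' @param covariate_names Character vector of covariate column names (may be
#'   empty).
#' @param family `"gaussian"` or `"binomial"`.
#' @return A list of class `phenocov` with elements `samples`, `phenotype`,
#'   `covariates` (n x c numeric matrix, c may be 0) and `family`.
#' @export
read_phenocov <- function(path, phenotype_name, covariate_names = character(),
                          family = c("gaussian", "binomial")) {
  family <- match.arg(family)
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  nm <- tolower(names(tab))
  ii <- which(nm %in% c("iid", "sample", "sample_id", "sampleid", "id"))[1]
  if (is.na(ii)) ii <- 1L
  if (!phenotype_name %in% names(tab))
    stop("phenotype column '", phenotype_name, "' not found")
  miss_cov <- setdiff(covariate_names, names(tab))
  if (length(miss_cov))
    stop("covariate column(s) not found: ", paste(miss_cov, collapse = ", "))
  y <- tab[[phenotype_name]]
  covs <- if (length(covariate_names))
    as.matrix(tab[, covariate_names, drop = FALSE]) else
    matrix(numeric(), nrow(tab), 0)
  storage.mode(covs) <- "double"
  keep <- !is.na(y) & stats::complete.cases(covs)
  n_drop <- sum(!keep)
  if (n_drop) message(n_drop, " sample(s) dropped for missing phenotype/covariates")
  y <- as.numeric(y[keep])
  covs <- covs[keep, , drop = FALSE]
  samples <- as.character(tab[[ii]])[keep]
  if (family == "binomial") {
    u <- sort(unique(y))
    if (identical(u, c(1, 2))) {
      warning("binary phenotype coded 1/2 remapped to 0/1")
      y <- y - 1
    }
    if (!all(y %in% c(0, 1)))
      stop("binary phenotype must be coded 0/1 (or 1/2)")
    if (length(unique(y)) < 2L)
      stop("binary phenotype has a single class")
  }
  structure(list(samples = samples, phenotype = y, covariates = covs,
                 family = family), class = "phenocov")
}

# Decode a vector of GT strings ("0/1", "1|2", "./.", "0") into counts of
# the k-th ALT allele; NA where any allele call is missing.
.gt_alt_count <- function(gt, k) {
  gt[is.na(gt)] <- "."
  gt <- sub(":.*$", "", gt)
  al <- strsplit(gt, "[/|]")
  vapply(al, function(a) {
    if (length(a) == 0L || anyNA(a) || any(a == "." | a == ""))
      return(NA_real_)
    sum(a == as.character(k))
  }, numeric(1))
}

#' Read genotypes for one region from a VCF file
#'
#' Extracts all variant records with `start <= POS <= end` on the region's
#' chromosome and returns per-sample dosages of each ALT allele. Multiallelic
#' records are split into one column per ALT allele; split ids are
#' `<original_id>_<ALT>` and missing VCF ids are synthesized as
#' `<chrom>:<pos>:<ref>:<alt>`. Missing genotypes are imputed to the column
#' mean (columns exceeding the missingness limit are pruned later by
#' [filter_variants()]). With `genotype_field = "DS"` the dosage field is used
#' verbatim (comma-split per ALT for multiallelic records).
#'
#' @param path VCF file (plain text or bgzip; anything [vcfR::read.vcfR()]
#'   reads).
#' @param region A single-row `region_def` (or list with `chrom`, `start`,
#'   `end`).
#' @param genotype_field `"GT"` (allele counts) or `"DS"` (dosages).
#' @return A `genotype_block`: list with `samples`, `dosage` (n x m matrix in
#'   \[0,2\], columns ordered by position then ALT), `variants` (data.frame of
#'   variant metadata) and `missingness` (pre-imputation missing fraction per
#'   column).
#' @export
read_vcf_region <- function(path, region, genotype_field = c("GT", "DS")) {
  genotype_field <- match.arg(genotype_field)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  pos <- as.integer(fix[, "POS"])
  sel <- which(fix[, "CHROM"] == as.character(region$chrom) &
               pos >= region$start & pos <= region$end)
  samples <- colnames(vcf@gt)[-1]
  empty <- function() structure(list(
    samples = samples,
    dosage = matrix(numeric(), length(samples), 0),
    variants = data.frame(variant_id = character(), chrom = character(),
                          pos = integer(), ref = character(), alt = character(),
                          maf = numeric(), source_multiallelic = logical(),
                          flipped_to_minor = logical(), stringsAsFactors = FALSE),
    missingness = numeric()), class = "genotype_block")
  if (length(sel) == 0L) return(empty())
  gtmat <- vcfR::extract.gt(vcf, element = genotype_field)
  if (is.null(dim(gtmat)))
    gtmat <- matrix(gtmat, nrow = 1, dimnames = list(NULL, samples))
  cols <- list(); meta <- list(); missfrac <- numeric()
  for (i in sel) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    multi <- length(alts) > 1L
    vid <- fix[i, "ID"]
    field_i <- gtmat[i, ]
    ds_parts <- if (genotype_field == "DS") strsplit(field_i, ",", fixed = TRUE)
    for (k in seq_along(alts)) {
      if (genotype_field == "GT") {
        d <- .gt_alt_count(field_i, k)
      } else {
        d <- vapply(ds_parts, function(p) {
          if (length(p) < k || p[k] %in% c(".", "")) NA_real_ else as.numeric(p[k])
        }, numeric(1))
      }
      mf <- mean(is.na(d))
      if (anyNA(d)) {
        mu <- mean(d, na.rm = TRUE)
        if (is.nan(mu)) mu <- 0
        d[is.na(d)] <- mu
      }
      id_k <- if (is.na(vid) || vid == ".")
        paste(fix[i, "CHROM"], pos[i], fix[i, "REF"], alts[k], sep = ":")
      else if (multi) paste0(vid, "_", alts[k]) else vid
      cols[[length(cols) + 1L]] <- d
      missfrac[length(missfrac) + 1L] <- mf
      meta[[length(meta) + 1L]] <- data.frame(
        variant_id = id_k, chrom = fix[i, "CHROM"], pos = pos[i],
        ref = fix[i, "REF"], alt = alts[k], maf = NA_real_,
        source_multiallelic = multi, flipped_to_minor = FALSE,
        stringsAsFactors = FALSE)
    }
  }
  variants <- do.call(rbind, meta)
  dosage <- do.call(cbind, cols)
  rownames(dosage) <- samples
  ord <- order(variants$pos, variants$alt, variants$variant_id)
  variants <- variants[ord, , drop = FALSE]
  dosage <- dosage[, ord, drop = FALSE]
  missfrac <- missfrac[ord]
  rownames(variants) <- NULL
  if (anyDuplicated(variants$variant_id))
    variants$variant_id <- make.unique(variants$variant_id, sep = "_dup")
  colnames(dosage) <- variants$variant_id
  if (any(dosage < 0 | dosage > 2))
    stop("dosage values outside [0,2] in region ", region$chrom, ":",
         region$start, "-", region$end)
  structure(list(samples = samples, dosage = dosage, variants = variants,
                 missingness = missfrac), class = "genotype_block")
}

#' Align a genotype block and phenotypes on the shared sample set
#'
#' Restricts both objects to the intersection of their sample IDs, in VCF
#' (block) order, and reports dropped counts.
#'
#' @param block A `genotype_block`.
#' @param pheno A `phenocov`.
#' @return List with the aligned `block` and `pheno`.
#' @export
align_samples <- function(block, pheno) {
  common <- intersect(block$samples, pheno$samples)
  if (length(common) == 0L) stop("no overlapping samples between VCF and phenotypes")
  dg <- length(block$samples) - length(common)
  dp <- length(pheno$samples) - length(common)
  if (dg || dp)
    message(dg, " VCF sample(s) and ", dp,
            " phenotype sample(s) dropped (no overlap)")
  gi <- match(common, block$samples)
  pi_ <- match(common, pheno$samples)
  block$samples <- common
  block$dosage <- block$dosage[gi, , drop = FALSE]
  pheno$samples <- common
  pheno$phenotype <- pheno$phenotype[pi_]
  pheno$covariates <- pheno$covariates[pi_, , drop = FALSE]
  list(block = block, pheno = pheno)
}
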