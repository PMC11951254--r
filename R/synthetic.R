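#' Simulate a block-LD genotype matrix at given allele frequencies
#'
#' Draws a latent multivariate normal with block-exchangeable correlation
#' (variants in the same block share a latent factor with loading
#' `sqrt(rho)`) and thresholds each variant at the Hardy-Weinberg genotype
#' quantiles implied by its allele frequency: `P(0) = (1-p)^2`,
#' `P(1) = 2p(1-p)`, `P(2) = p^2`, with cut points at the standard-normal
#' quantiles of the cumulative probabilities. Thresholding attenuates the
#' latent correlation, so the dosage correlation is somewhat below `rho`.
#'
#' @param n Number of samples.
#' @param mafs Allele frequencies of the counted allele, in (0, 0.5].
#' @param blocks List of `list(idx = <variant indices>, rho = <within-block
#'   latent correlation in [0,1)>)`; variants outside any block are
#'   independent.
#' @param seed Integer seed (reproducible for a fixed seed).
#' @param chrom Chromosome name for the variant metadata.
#' @param pos Positions (default `1000, 2000, ...`).
#' @return A `genotype_block`.
#' @export
simulate_genotypes <- function(n, mafs, blocks = list(), seed = 1,
                               chrom = "1", pos = NULL) {
  m <- length(mafs)
  stopifnot(all(mafs > 0), all(mafs <= 0.5), n >= 1)
  for (b in blocks) {
    if (is.null(b$idx) || is.null(b$rho) || b$rho < 0 || b$rho >= 1)
      stop("block specification must have idx and rho in [0,1) ",
           "(exchangeable correlation is not positive definite otherwise)")
    if (any(b$idx < 1 | b$idx > m)) stop("block index out of range")
  }
  if (anyDuplicated(unlist(lapply(blocks, `[[`, "idx"))))
    stop("blocks must not overlap")
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  set.seed(seed)
  Z <- matrix(stats::rnorm(n * m), n, m)
  for (b in blocks) {
    f <- stats::rnorm(n)
    Z[, b$idx] <- sqrt(b$rho) * f +
      sqrt(1 - b$rho) * Z[, b$idx, drop = FALSE]
  }
  dosage <- matrix(0, n, m)
  for (j in seq_len(m)) {
    p <- mafs[j]
    c1 <- stats::qnorm((1 - p)^2)
    c2 <- stats::qnorm((1 - p)^2 + 2 * p * (1 - p))
    dosage[, j] <- (Z[, j] >= c1) + (Z[, j] >= c2)
  }
  samples <- sprintf("S%04d", seq_len(n))
  rownames(dosage) <- samples
  variants <- data.frame(
    variant_id = sprintf("rs%d", seq_len(m)),
    chrom = chrom, pos = as.integer(pos), ref = "A", alt = "G",
    maf = NA_real_, source_multiallelic = FALSE, flipped_to_minor = FALSE,
    stringsAsFactors = FALSE)
  colnames(dosage) <- variants$variant_id
  structure(list(samples = samples, dosage = dosage, variants = variants,
                 missingness = rep(0, m)), class = "genotype_block")
}

#' Simulate a phenotype from a genotype block
#'
#' Gaussian: `y = G beta + X gamma + eps` with the stated residual variance.
#' Binomial: a logistic model whose intercept is solved numerically so the
#' expected case fraction matches `target` to within 0.005 — this is how
#' unbalanced case/control designs are emulated.
#'
#' @param block A `genotype_block`.
#' @param causal Named numeric vector of effects, names matching variant ids
#'   (empty for the global null).
#' @param X Optional covariate matrix.
#' @param covar_beta Covariate effects (default 0).
#' @param family `"gaussian"` or `"binomial"`.
#' @param target Residual variance (gaussian, default 1) or expected case
#'   fraction in (0,1) (binomial, default 0.5).
#' @param seed Integer seed.
#' @return Numeric phenotype vector (0/1 for binomial).
#' @export
simulate_phenotype <- function(block, causal = numeric(), X = NULL,
                               covar_beta = NULL,
                               family = c("gaussian", "binomial"),
                               target = if (family[1] == "gaussian") 1 else 0.5,
                               seed = 1) {
  family <- match.arg(family)
  n <- nrow(block$dosage)
  eta <- rep(0, n)
  if (length(causal)) {
    idx <- match(names(causal), block$variants$variant_id)
    if (anyNA(idx)) stop("causal variant(s) not in block: ",
                         paste(names(causal)[is.na(idx)], collapse = ", "))
    eta <- eta + drop(block$dosage[, idx, drop = FALSE] %*% causal)
  }
  if (!is.null(X)) {
    X <- as.matrix(X)
    if (is.null(covar_beta)) covar_beta <- rep(0, ncol(X))
    eta <- eta + drop(X %*% covar_beta)
  }
  set.seed(seed)
  if (family == "gaussian") {
    stopifnot(target >= 0)
    eta + stats::rnorm(n, sd = sqrt(target))
  } else {
    stopifnot(target > 0, target < 1)
    frac <- function(b0) mean(stats::plogis(b0 + eta)) - target
    lo <- -50; hi <- 50
    if (frac(lo) > 0.005 || frac(hi) < -0.005)
      stop("target case fraction unreachable for the given effects")
    b0 <- stats::uniroot(frac, c(lo, hi), tol = 1e-10)$root
    if (abs(frac(b0)) > 0.005)
      stop("intercept search failed to match target case fraction")
    stats::rbinom(n, 1, stats::plogis(b0 + eta))
  }
}

#' Write a genotype block, region table and phenotypes as analysis fixtures
#'
#' Emits a valid VCF 4.2 (plain text, GT field; optional DS equal to the
#' dosage), a tab-separated region table and a phenotype/covariate table that
#' [read_vcf_region()], [read_region_definitions()] and [read_phenocov()]
#' round-trip exactly. Optionally appends a synthetic triallelic record to
#' exercise multiallelic splitting.
#'
#' @param block A `genotype_block` with integer dosages (required for GT).
#' @param regions A `region_def` data.frame.
#' @param phenotype Phenotype vector aligned with the block samples.
#' @param covariates Optional covariate matrix (written alongside).
#' @param prefix Output path prefix; writes `<prefix>.vcf`,
#'   `<prefix>.regions.tsv`, `<prefix>.pheno.tsv`.
#' @param with_ds Also write a DS field equal to the dosage.
#' @param add_multiallelic Append a triallelic record (REF=A, ALT=C,T) after
#'   the last variant.
#' @param seed Seed for the multiallelic genotypes.
#' @return Invisibly, the three file paths.
#' @export
write_fixture <- function(block, regions, phenotype, covariates = NULL,
                          prefix, with_ds = FALSE, add_multiallelic = FALSE,
                          seed = 1) {
  d <- block$dosage
  if (any(d != round(d))) stop("GT output requires integer dosages")
  samples <- block$samples
  gt_str <- c("0/0", "0/1", "1/1")
  fmt <- if (with_ds) "GT:DS" else "GT"
  recs <- character(nrow(block$variants))
  for (j in seq_len(nrow(block$variants))) {
    v <- block$variants[j, ]
    g <- gt_str[d[, j] + 1L]
    if (with_ds) g <- paste0(g, ":", format(d[, j], trim = TRUE))
    recs[j] <- paste(c(v$chrom, v$pos, v$variant_id, v$ref, v$alt, ".",
                       "PASS", ".", fmt, g), collapse = "\t")
  }
  if (add_multiallelic) {
    set.seed(seed)
    chrom <- block$variants$chrom[1]
    pos <- max(block$variants$pos) + 100L
    # two ALT alleles at frequencies 0.15 and 0.25
    draw <- function() sample(0:2, 2, replace = TRUE, prob = c(0.6, 0.15, 0.25))
    g <- vapply(seq_along(samples), function(i) {
      a <- sort(draw()); paste0(a[1], "/", a[2])
    }, character(1))
    if (with_ds) {
      ds <- vapply(strsplit(g, "/"), function(a)
        paste(sum(a == "1"), sum(a == "2"), sep = ","), character(1))
      g <- paste0(g, ":", ds)
    }
    recs <- c(recs, paste(c(chrom, pos, "rsM", "A", "C,T", ".", "PASS", ".",
                            fmt, g), collapse = "\t"))
  }
  vcf_path <- paste0(prefix, ".vcf")
  hdr <- c("##fileformat=VCFv4.2",
           paste0("##contig=<ID=", unique(block$variants$chrom), ">"),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           if (with_ds)
             '##FORMAT=<ID=DS,Number=A,Type=Float,Description="Dosage">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, recs), vcf_path)
  reg_path <- paste0(prefix, ".regions.tsv")
  utils::write.table(
    data.frame(chr = regions$chrom, start = regions$start, end = regions$end,
               region_id = regions$region_id),
    reg_path, sep = "\t", quote = FALSE, row.names = FALSE)
  ph_path <- paste0(prefix, ".pheno.tsv")
  ph <- data.frame(IID = samples, pheno = phenotype)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (is.null(colnames(covariates)))
      colnames(covariates) <- paste0("cov", seq_len(ncol(covariates)))
    ph <- cbind(ph, covariates)
  }
  utils::write.table(ph, ph_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(vcf = vcf_path, regions = reg_path, pheno = ph_path))
}
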