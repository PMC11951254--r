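#' Default pipeline configuration
#'
#' @param ... Overrides for any default field.
#' @return Named list of configuration values for [run_regscan()].
#' @export
regscan_config <- function(...) {
  cfg <- list(vcf = NULL, regions = NULL, pheno = NULL,
              phenotype_name = "pheno", covariates = character(),
              family = "gaussian", tests = .region_tests,
              maf_min = 0.01, miss_max = 0.05, prune_r2 = 0.98,
              bin_r2 = 0.5, pc_var = 0.8, skat_weights = "flat",
              firth = FALSE, threads = 1L, seed = 1L,
              out_prefix = "regscan", genotype_field = "GT",
              intermediates_dir = NULL, write_allsnps = TRUE,
              write_covariates = TRUE, log_level = "info")
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

# read a simple key=value config file; '#' comments allowed
read_config_file <- function(path) {
  ln <- readLines(path)
  ln <- sub("#.*$", "", ln)
  ln <- trimws(ln[nzchar(trimws(ln))])
  kv <- strsplit(ln, "=", fixed = TRUE)
  out <- list()
  for (p in kv) {
    if (length(p) < 2) stop("malformed config line: ", paste(p, collapse = "="))
    key <- trimws(p[1]); val <- trimws(paste(p[-1], collapse = "="))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num
    else if (val %in% c("TRUE", "FALSE", "true", "false"))
      as.logical(toupper(val))
    else if (grepl(",", val)) strsplit(val, ",")[[1]]
    else val
  }
  out
}

# Analyze one region: filter -> prune -> bin -> recode -> fits -> all tests.
# Returns the four row sets for this region (plus optional allsnps/covs).
analyze_region <- function(block, pheno, region, cfg,
                           already_assigned = character()) {
  rid <- as.character(region$region_id)
  na_region_row <- function(n_input, n_analyzed = 0L, n_bins = NA_integer_) {
    row <- data.frame(region_id = rid, chrom = region$chrom,
                      start = region$start, end = region$end,
                      n_variants_input = n_input,
                      n_variants_analyzed = n_analyzed, n_bins = n_bins,
                      stringsAsFactors = FALSE)
    for (tn in .region_tests) {
      row[[paste0(tn, "_stat")]] <- NA_real_
      row[[paste0(tn, "_df")]] <- NA_real_
      row[[paste0(tn, "_p")]] <- NA_real_
    }
    row$MINP_RAW <- NA_real_
    row$ACAT_P <- NA_real_
    row
  }
  empty <- list(
    bins = data.frame(region_id = character(), bin_id = integer(),
                      n_variants = integer(), estimate = numeric(),
                      se = numeric(), stat = numeric(), p = numeric(),
                      stringsAsFactors = FALSE),
    variants = data.frame(),
    pruned = data.frame(region_id = character(), variant_id = character(),
                        reason = character(), stringsAsFactors = FALSE),
    allsnps = NULL, covariates = NULL)

  n_input <- ncol(block$dosage)
  if (n_input == 0L)
    return(c(list(region = na_region_row(0L)), empty,
             assigned = list(character())))

  # cross-region duplicate assignment: earlier region wins
  key <- paste(block$variants$chrom, block$variants$pos,
               block$variants$variant_id, sep = ":")
  dup <- key %in% already_assigned
  dup_log <- if (any(dup))
    data.frame(region_id = rid,
               variant_id = block$variants$variant_id[dup],
               reason = "DUPLICATE", stringsAsFactors = FALSE)
  else empty$pruned
  block$dosage <- block$dosage[, !dup, drop = FALSE]
  block$variants <- block$variants[!dup, , drop = FALSE]
  block$missingness <- block$missingness[!dup]

  fl <- filter_variants(block, cfg$maf_min, cfg$miss_max, region_id = rid)
  blk <- fl$block
  prune_log <- rbind(dup_log, fl$prune_log)
  if (ncol(blk$dosage) == 0L)
    return(c(list(region = na_region_row(n_input)),
             empty[c("bins", "variants")],
             list(pruned = prune_log, allsnps = NULL, covariates = NULL),
             assigned = list(key)))

  y <- pheno$phenotype
  X <- if (ncol(pheno$covariates)) pheno$covariates else NULL
  family <- pheno$family

  # pre-pruning single-variant tests (optional allsnps output)
  sv_all <- single_variant_tests(y, blk$dosage, X, family, cfg$firth)
  allsnps <- if (isTRUE(cfg$write_allsnps))
    cbind(data.frame(region_id = rid, stringsAsFactors = FALSE),
          sv_all[, "variant_id", drop = FALSE],
          blk$variants[, c("chrom", "pos", "maf")],
          sv_all[, c("beta", "se", "p")])
  else NULL

  corr_all <- pairwise_correlation(blk)
  pr <- ld_prune(corr_all, blk$variants, cfg$prune_r2, region_id = rid)
  prune_log <- rbind(prune_log, pr$prune_log)
  kept <- pr$keep
  kblk <- blk
  kblk$dosage <- blk$dosage[, kept, drop = FALSE]
  kblk$variants <- blk$variants[kept, , drop = FALSE]
  kblk$missingness <- blk$missingness[kept]
  m <- length(kept)

  bins <- clique_bins(corr_all[kept, kept, drop = FALSE], cfg$bin_r2)
  rec <- recode_bins_positive(kblk, bins)
  kblk <- rec$block; bins <- rec$bins
  W <- bin_contrast_matrix(bins, m, signs_absorbed = TRUE)
  vif <- tryCatch(suppressWarnings(compute_vif(kblk)),
                  error = function(e) rep(NA_real_, m))

  weights <- if (identical(cfg$skat_weights, "beta"))
    skat_beta_weights(kblk$variants$maf) else rep(1, m)

  row <- na_region_row(n_input, m, bins$n_bins)
  fit <- tryCatch(fit_joint(y, kblk$dosage, X, family, cfg$firth),
                  error = function(e) NULL)
  bin_rows <- empty$bins
  sv_kept <- sv_all[kept, , drop = FALSE]
  run <- function(name, expr) {
    if (!name %in% cfg$tests) return(NULL)
    tryCatch(expr, error = function(e) NULL)
  }
  res <- list()
  if (!is.null(fit)) {
    res$WALD <- run("WALD", wald_region_test(fit))
    mlc <- run("MLC", mlc_test(fit, W))
    if (!is.null(mlc)) {
      res$MLC <- mlc$region
      if (nrow(mlc$bins))
        bin_rows <- cbind(data.frame(region_id = rid,
                                     stringsAsFactors = FALSE), mlc$bins)
    }
    # LC: global positive recoding relative to the first variant
    rc <- pairwise_correlation(kblk)
    signs <- ifelse(rc[1, ] < 0, -1, 1)
    res$LC <- run("LC", lc_test(fit, signs))
  }
  res$PC80 <- run("PC80",
                  pc80_test(y, kblk$dosage, X, family, cfg$pc_var, cfg$firth))
  res$SKAT <- run("SKAT", skat_test(y, kblk$dosage, X, family, weights))
  res$SKATO <- run("SKATO", skat_o_test(y, kblk$dosage, X, family, weights))
  res$SIMPLEM <- run("SIMPLEM",
                     simple_m(pairwise_correlation(kblk), sv_kept$p))
  res$GATES <- run("GATES", gates(pairwise_correlation(kblk), sv_kept$p))
  for (tn in names(res)) {
    if (is.null(res[[tn]])) next
    row[[paste0(tn, "_stat")]] <- res[[tn]]$stat
    row[[paste0(tn, "_df")]] <- res[[tn]]$df
    row[[paste0(tn, "_p")]] <- res[[tn]]$p
  }
  row$MINP_RAW <- if (all(is.na(sv_kept$p))) NA_real_ else
    min(sv_kept$p, na.rm = TRUE)
  region_ps <- unlist(lapply(.region_tests,
                             function(tn) row[[paste0(tn, "_p")]]))
  row$ACAT_P <- if (all(is.na(region_ps))) NA_real_ else
    cauchy_combine(region_ps[!is.na(region_ps)])

  # variant-level rows: analyzed variants get bins/joint stats; LD-pruned
  # variants keep metadata and single-variant results with NA bin
  joint <- data.frame(beta_joint = NA_real_, se_joint = NA_real_,
                      p_joint = NA_real_)[rep(1, ncol(blk$dosage)), ]
  if (!is.null(fit) && fit$converged && m > 0) {
    se_j <- sqrt(pmax(diag(fit$cov_hat), 0))
    z2 <- (fit$beta_hat / se_j)^2
    pj <- if (family == "gaussian")
      stats::pf(z2, 1, fit$residual_df, lower.tail = FALSE)
    else stats::pchisq(z2, 1, lower.tail = FALSE)
    joint$beta_joint[kept] <- fit$beta_hat
    joint$se_joint[kept] <- se_j
    joint$p_joint[kept] <- pj
  }
  bin_col <- rep(NA_integer_, ncol(blk$dosage))
  bin_col[kept] <- bins$bin_of
  flip_col <- blk$variants$flipped_to_minor
  flip_col[kept] <- kblk$variants$flipped_to_minor
  vif_col <- rep(NA_real_, ncol(blk$dosage))
  vif_col[kept] <- vif
  variants <- data.frame(
    region_id = rid, variant_id = blk$variants$variant_id,
    chrom = blk$variants$chrom, pos = blk$variants$pos,
    ref = blk$variants$ref, alt = blk$variants$alt,
    maf = blk$variants$maf, bin_id = bin_col, flipped = flip_col,
    beta_single = sv_all$beta, se_single = sv_all$se, p_single = sv_all$p,
    beta_joint = joint$beta_joint, se_joint = joint$se_joint,
    p_joint = joint$p_joint, vif = vif_col, stringsAsFactors = FALSE)

  covrows <- NULL
  if (isTRUE(cfg$write_covariates) && !is.null(fit) && !is.null(X)) {
    ci <- seq.int(2, length.out = ncol(X))
    covrows <- data.frame(
      region_id = rid, term = fit$term_names[ci],
      beta = unname(fit$all_beta[ci]),
      se = sqrt(pmax(diag(fit$all_cov)[ci], 0)), stringsAsFactors = FALSE)
    z2 <- (covrows$beta / covrows$se)^2
    covrows$p <- if (family == "gaussian")
      stats::pf(z2, 1, fit$residual_df, lower.tail = FALSE)
    else stats::pchisq(z2, 1, lower.tail = FALSE)
  }
  list(region = row, bins = bin_rows, variants = variants,
       pruned = prune_log, allsnps = allsnps, covariates = covrows,
       assigned = key)
}

#' Materialize per-region dosage and variant-metadata intermediates
#'
#' Extracts each region from the VCF once and writes
#' `<dir>/region_<id>.data.tsv` (samples x variants dosage) and
#' `<dir>/region_<id>.snpinfo.tsv` (variant metadata), which
#' [run_regscan()] can consume instead of the VCF with identical results —
#' useful to bound memory on large inputs.
#'
#' @param vcf VCF path.
#' @param regions A `region_def` table (or path to one).
#' @param dir Output directory (created if needed).
#' @param genotype_field `"GT"` or `"DS"`.
#' @return Invisibly, a data.frame of written paths per region.
#' @export
recode_vcf <- function(vcf, regions, dir, genotype_field = "GT") {
  if (is.character(regions)) regions <- read_region_definitions(regions)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  out <- lapply(seq_len(nrow(regions)), function(i) {
    reg <- regions[i, ]
    blk <- read_vcf_region(vcf, reg, genotype_field)
    if (ncol(blk$dosage) == 0L)
      warning("region ", reg$region_id, " has no variants in ", vcf)
    dpath <- file.path(dir, paste0("region_", reg$region_id, ".data.tsv"))
    spath <- file.path(dir, paste0("region_", reg$region_id, ".snpinfo.tsv"))
    dd <- data.frame(IID = blk$samples, blk$dosage, check.names = FALSE,
                     stringsAsFactors = FALSE)
    utils::write.table(dd, dpath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    si <- cbind(blk$variants,
                missingness = if (length(blk$missingness))
                  blk$missingness else numeric(0))
    utils::write.table(si, spath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    data.frame(region_id = reg$region_id, data = dpath, snpinfo = spath,
               stringsAsFactors = FALSE)
  })
  invisible(do.call(rbind, out))
}

# rebuild a genotype_block from recode_vcf intermediates
.read_intermediates <- function(dir, region_id) {
  dpath <- file.path(dir, paste0("region_", region_id, ".data.tsv"))
  spath <- file.path(dir, paste0("region_", region_id, ".snpinfo.tsv"))
  if (!file.exists(dpath) || !file.exists(spath))
    stop("intermediates for region ", region_id, " not found in ", dir)
  dd <- utils::read.table(dpath, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  si <- utils::read.table(spath, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  samples <- as.character(dd$IID)
  dosage <- as.matrix(dd[, -1, drop = FALSE])
  rownames(dosage) <- samples
  miss <- if ("missingness" %in% names(si)) si$missingness else
    rep(0, nrow(si))
  si$missingness <- NULL
  structure(list(samples = samples, dosage = dosage, variants = si,
                 missingness = miss), class = "genotype_block")
}

#' Run the full region-level association pipeline
#'
#' For each region: read genotypes (from the VCF or from [recode_vcf()]
#' intermediates), filter and recode on MAF, LD-prune, assign LD bins and
#' sign-recode, fit the joint model, and compute the eight region-level
#' tests, bin-level tests and single-variant tests. Regions are independent
#' tasks; outputs are merged in region order so results are byte-identical
#' for any worker count. A failing region yields an NA row and a complete
#' prune log rather than aborting the run.
#'
#' @param cfg Configuration from [regscan_config()] (or a config-file path;
#'   explicit arguments in `...` override file values).
#' @param ... Field overrides applied on top of `cfg`.
#' @return Invisibly, a list with the assembled `results` data.frames, the
#'   written `paths`, and `n_failed`.
#' @export
run_regscan <- function(cfg = regscan_config(), ...) {
  if (is.character(cfg)) cfg <- do.call(regscan_config, read_config_file(cfg))
  over <- list(...)
  if (length(over)) cfg[names(over)] <- over
  regions <- if (is.character(cfg$regions))
    read_region_definitions(cfg$regions) else cfg$regions
  if (is.null(regions) || nrow(regions) == 0L) stop("zero regions")
  pheno <- if (is.character(cfg$pheno))
    read_phenocov(cfg$pheno, cfg$phenotype_name, cfg$covariates, cfg$family)
  else cfg$pheno

  get_block <- function(reg) {
    if (!is.null(cfg$intermediates_dir))
      .read_intermediates(cfg$intermediates_dir, reg$region_id)
    else read_vcf_region(cfg$vcf, reg, cfg$genotype_field)
  }
  worker <- function(i) {
    reg <- regions[i, ]
    tryCatch({
      blk <- get_block(reg)
      al <- align_samples(blk, pheno)
      list(block = al$block, pheno = al$pheno, reg = reg, error = NULL)
    }, error = function(e)
      list(block = NULL, pheno = NULL, reg = reg,
           error = conditionMessage(e)))
  }
  idx <- seq_len(nrow(regions))
  loaded <- if (cfg$threads > 1L && .Platform$OS.type == "unix")
    parallel::mclapply(idx, worker, mc.cores = cfg$threads)
  else lapply(idx, worker)

  # duplicate resolution and analysis are sequential in region order, so
  # results do not depend on the worker count
  assigned <- character()
  out <- vector("list", length(idx))
  n_failed <- 0L
  for (i in idx) {
    L <- loaded[[i]]
    reg <- L$reg
    res <- if (is.null(L$error)) {
      tryCatch(analyze_region(L$block, L$pheno, reg, cfg, assigned),
               error = function(e) NULL)
    } else NULL
    if (is.null(res)) {
      n_failed <- n_failed + 1L
      res <- analyze_region(
        structure(list(samples = character(),
                       dosage = matrix(numeric(), 0, 0),
                       variants = data.frame(), missingness = numeric()),
                  class = "genotype_block"),
        pheno, reg, cfg)
      if (cfg$log_level != "quiet")
        message("region ", reg$region_id, " failed: ",
                if (!is.null(L$error)) L$error else "analysis error")
    } else {
      assigned <- c(assigned, res$assigned)
    }
    if (cfg$log_level == "info")
      message(sprintf(
        "region %s: input=%d analyzed=%d pruned=%d bins=%s",
        reg$region_id, res$region$n_variants_input,
        res$region$n_variants_analyzed, nrow(res$pruned),
        ifelse(is.na(res$region$n_bins), "NA", res$region$n_bins)))
    out[[i]] <- res
  }
  if (n_failed == length(idx)) stop("all regions failed")
  bind <- function(field) {
    parts <- Filter(function(x) !is.null(x) && nrow(x) > 0,
                    lapply(out, `[[`, field))
    if (!length(parts)) return(NULL)
    do.call(rbind, parts)
  }
  results <- list(region = do.call(rbind, lapply(out, `[[`, "region")),
                  bins = bind("bins"), variants = bind("variants"),
                  pruned = bind("pruned"))
  if (is.null(results$bins))
    results$bins <- data.frame(region_id = character(), bin_id = integer(),
                               n_variants = integer(), estimate = numeric(),
                               se = numeric(), stat = numeric(),
                               p = numeric())
  if (is.null(results$variants))
    results$variants <- data.frame(region_id = character(),
                                   variant_id = character())
  if (is.null(results$pruned))
    results$pruned <- data.frame(region_id = character(),
                                 variant_id = character(),
                                 reason = character())
  if (isTRUE(cfg$write_allsnps)) results$allsnps <- bind("allsnps")
  if (isTRUE(cfg$write_covariates)) results$covariates <- bind("covariates")
  paths <- write_outputs(results, cfg$out_prefix)
  invisible(list(results = results, paths = paths, n_failed = n_failed))
}
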