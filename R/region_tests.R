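.test_result <- function(name, stat = NA_real_, df = NA_real_, p = NA_real_) {
  list(name = name, stat = as.numeric(stat), df = as.numeric(df),
       p = as.numeric(p))
}

# quadratic form b' V^{-1} b, NULL on singular V
.quad_form <- function(b, V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  z <- backsolve(ch, b, transpose = TRUE)
  sum(z^2)
}

#' Full-df multiple-regression Wald region test
#'
#' `T = beta' V^{-1} beta` over all m variant coefficients of a joint fit.
#' Binary traits refer T to a chi-square with m df; gaussian traits use the
#' small-sample F form `T/m ~ F(m, residual_df)`.
#'
#' @param fit A `joint_fit` from [fit_joint()].
#' @return A test-result list (`name`, `stat`, `df`, `p`).
#' @export
wald_region_test <- function(fit) {
  m <- length(fit$beta_hat)
  if (m == 0L || !fit$converged) return(.test_result("WALD"))
  Tq <- .quad_form(fit$beta_hat, fit$cov_hat)
  if (is.null(Tq)) return(.test_result("WALD"))
  if (fit$family == "gaussian") {
    Fs <- Tq / m
    .test_result("WALD", Fs, m,
                 stats::pf(Fs, m, fit$residual_df, lower.tail = FALSE))
  } else {
    .test_result("WALD", Tq, m, stats::pchisq(Tq, m, lower.tail = FALSE))
  }
}

#' MLC region test on LD-bin contrasts, with bin-level tests
#'
#' With contrast matrix W (one row per bin), `L = W beta`, `S = W V W'`, and
#' the region statistic is `T = L' S^{-1} L` on B df (F form
#' `T/B ~ F(B, residual_df)` for gaussian traits). Each bin b additionally
#' gets a 1-df test of `L_b` with `se = sqrt(S_bb)` and a chi-square
#' reference. T is invariant to positive rescaling of W's rows.
#'
#' @param fit A `joint_fit`.
#' @param W B x m contrast matrix of full row rank, B <= m.
#' @return List with `region` (test-result, name `MLC`) and `bins`
#'   (data.frame `bin_id`, `n_variants`, `estimate`, `se`, `stat`, `p`).
#' @export
mlc_test <- function(fit, W) {
  W <- as.matrix(W)
  B <- nrow(W)
  nvar <- rowSums(W != 0)
  empty_bins <- data.frame(bin_id = integer(), n_variants = integer(),
                           estimate = numeric(), se = numeric(),
                           stat = numeric(), p = numeric())
  if (length(fit$beta_hat) == 0L || !fit$converged)
    return(list(region = .test_result("MLC"), bins = empty_bins))
  stopifnot(ncol(W) == length(fit$beta_hat), B <= ncol(W))
  L <- drop(W %*% fit$beta_hat)
  S <- W %*% fit$cov_hat %*% t(W)
  se <- sqrt(pmax(diag(S), 0))
  z2 <- (L / se)^2
  bins <- data.frame(bin_id = seq_len(B), n_variants = nvar, estimate = L,
                     se = se, stat = z2,
                     p = stats::pchisq(z2, 1, lower.tail = FALSE))
  Tq <- .quad_form(L, S)
  region <- if (is.null(Tq)) .test_result("MLC")
  else if (fit$family == "gaussian")
    .test_result("MLC", Tq / B, B,
                 stats::pf(Tq / B, B, fit$residual_df, lower.tail = FALSE))
  else .test_result("MLC", Tq, B, stats::pchisq(Tq, B, lower.tail = FALSE))
  list(region = region, bins = bins)
}

#' 1-df LC burden-type region test
#'
#' The MLC test with all variants in a single bin after global
#' positive-correlation recoding: signs are taken relative to the first
#' variant and the contrast averages all signed coefficients.
#'
#' @param fit A `joint_fit`.
#' @param signs Optional +1/-1 vector from global positive recoding; default
#'   all +1 (appropriate when the block is already globally recoded).
#' @return A test-result list (`name` `LC`, df 1).
#' @export
lc_test <- function(fit, signs = NULL) {
  m <- length(fit$beta_hat)
  if (m == 0L) return(.test_result("LC"))
  if (is.null(signs)) signs <- rep(1, m)
  W <- matrix(signs / m, 1, m)
  res <- mlc_test(fit, W)$region
  res$name <- "LC"
  res
}

#' Principal-component region test (PC80)
#'
#' Column-standardizes G, takes the eigendecomposition of its correlation
#' matrix, keeps the smallest k whose cumulative eigenvalue fraction reaches
#' `var_explained`, and jointly tests the k PC scores in a regression with
#' the covariates (F reference for gaussian, chi-square for binomial).
#'
#' @inheritParams fit_joint
#' @param var_explained Target fraction of genotypic variance (default 0.8).
#' @return A test-result list (`name` `PC80`, df k).
#' @export
pc80_test <- function(y, G, X = NULL, family = c("gaussian", "binomial"),
                      var_explained = 0.8, firth = FALSE) {
  family <- match.arg(family)
  stopifnot(var_explained > 0, var_explained <= 1)
  G <- as.matrix(G)
  m <- ncol(G)
  if (m == 0L) return(.test_result("PC80"))
  Gs <- scale(G)
  eg <- eigen(stats::cor(G), symmetric = TRUE)
  k <- which(cumsum(eg$values) / m >= var_explained - 1e-12)[1]
  scores <- Gs %*% eg$vectors[, seq_len(k), drop = FALSE]
  colnames(scores) <- paste0("PC", seq_len(k))
  fit <- fit_joint(y, scores, X, family, firth)
  res <- wald_region_test(fit)
  res$name <- "PC80"
  res
}

#' All eight region-level tests on an analyzed dosage matrix
#'
#' Convenience wrapper for a filtered (polymorphic) dosage matrix: assigns LD
#' bins, sign-recodes, fits the joint model and returns the p-values of the
#' eight region-level tests (MLC, LC, Wald, PC80, SKAT, SKAT-O, simpleM,
#' GATES). The full pipeline with filtering, pruning and file outputs is
#' [run_regscan()].
#'
#' @inheritParams fit_joint
#' @param bin_r2 LD-bin edge threshold on squared correlation.
#' @param var_explained PC80 variance target.
#' @param weights SKAT weights (default flat).
#' @return Named numeric vector of eight p-values.
#' @export
region_level_tests <- function(y, G, X = NULL,
                               family = c("gaussian", "binomial"),
                               bin_r2 = 0.5, var_explained = 0.8,
                               weights = NULL, firth = FALSE) {
  family <- match.arg(family)
  G <- as.matrix(G)
  if (is.null(colnames(G))) colnames(G) <- paste0("g", seq_len(ncol(G)))
  blk <- structure(list(samples = as.character(seq_len(nrow(G))),
                        dosage = G,
                        variants = data.frame(
                          variant_id = colnames(G), chrom = "1",
                          pos = seq_len(ncol(G)), ref = "A", alt = "G",
                          maf = colMeans(G) / 2,
                          source_multiallelic = FALSE,
                          flipped_to_minor = FALSE,
                          stringsAsFactors = FALSE),
                        missingness = rep(0, ncol(G))),
                   class = "genotype_block")
  corr <- pairwise_correlation(blk)
  bins <- clique_bins(corr, bin_r2)
  rec <- recode_bins_positive(blk, bins)
  Gr <- rec$block$dosage
  W <- bin_contrast_matrix(rec$bins, ncol(G), signs_absorbed = TRUE)
  fit <- fit_joint(y, Gr, X, family, firth)
  corr_r <- pairwise_correlation(rec$block)
  signs <- ifelse(corr_r[1, ] < 0, -1, 1)
  sv <- single_variant_tests(y, G, X, family, firth)
  c(MLC = mlc_test(fit, W)$region$p,
    LC = lc_test(fit, signs)$p,
    WALD = wald_region_test(fit)$p,
    PC80 = pc80_test(y, G, X, family, var_explained, firth)$p,
    SKAT = skat_test(y, Gr, X, family, weights)$p,
    SKATO = skat_o_test(y, Gr, X, family, weights)$p,
    SIMPLEM = simple_m(corr, sv$p)$p,
    GATES = gates(corr, sv$p)$p)
}
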