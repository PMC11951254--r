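#' simpleM minP region test
#'
#' Estimates the effective number of independent tests `M_eff` as the
#' smallest k whose top-k eigenvalues of the variant correlation matrix
#' account for at least 99.5% of the total, then applies a Sidak-style
#' correction to the minimum single-variant p-value:
#' `p = 1 - (1 - min p)^M_eff`.
#'
#' @param corr Correlation matrix of the analyzed variants.
#' @param p_values Single-variant p-values aligned with `corr`; NAs dropped.
#' @param var_fraction Eigenvalue fraction defining `M_eff` (default 0.995).
#' @return A test-result list (`name` `SIMPLEM`, `df` = `M_eff`).
#' @export
simple_m <- function(corr, p_values, var_fraction = 0.995) {
  corr <- as.matrix(corr)
  ok <- !is.na(p_values)
  if (!any(ok)) return(.test_result("SIMPLEM"))
  corr <- corr[ok, ok, drop = FALSE]
  p_values <- p_values[ok]
  m <- nrow(corr)
  ev <- eigen(corr, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  m_eff <- which(cumsum(ev) / sum(ev) >= var_fraction - 1e-12)[1]
  pmin_ <- min(p_values)
  p <- 1 - (1 - pmin_)^m_eff
  .test_result("SIMPLEM", NA_real_, m_eff, p)
}

# polynomial map from genotype correlation to two-sided p-value correlation;
# the fit's small endpoint error at |r| = 1 is repaired so duplicated
# variants count as one test
.gates_p_corr <- function(r) {
  a <- abs(r)
  rp <- 0.2982 * a^6 - 0.0127 * a^5 + 0.0588 * a^4 + 0.0099 * a^3 +
    0.6281 * a^2 - 0.0009 * a
  rp[a > 0.9999] <- 1
  diag(rp) <- 1
  rp
}

# effective number of tests: |S| - sum over eigenvalues > 1 of (lambda - 1)
.me_number <- function(corr_sub) {
  k <- nrow(corr_sub)
  if (k == 1L) return(1)
  ev <- eigen(corr_sub, symmetric = TRUE, only.values = TRUE)$values
  k - sum(pmax(ev - 1, 0))
}

#' GATES extended-Simes region test
#'
#' Sorts the single-variant p-values ascending and returns
#' `min_j Me(all) * p_(j) / Me(top j)`, where `Me(S)` is the effective number
#' of tests of variant set S derived from the eigenvalues of the p-value
#' correlation submatrix. The correlation between two variants' p-values is
#' obtained from their genotype Pearson correlation through the published
#' sixth-degree polynomial approximation (perfectly correlated variants map
#' to 1); using the raw genotype correlation instead is anti-conservative
#' under strong LD.
#'
#' @inheritParams simple_m
#' @return A test-result list (`name` `GATES`).
#' @export
gates <- function(corr, p_values) {
  corr <- as.matrix(corr)
  ok <- !is.na(p_values)
  if (!any(ok)) return(.test_result("GATES"))
  corr <- .gates_p_corr(corr[ok, ok, drop = FALSE])
  p_values <- p_values[ok]
  ord <- order(p_values)
  ps <- p_values[ord]
  cs <- corr[ord, ord, drop = FALSE]
  m <- length(ps)
  me_all <- .me_number(cs)
  me_top <- vapply(seq_len(m), function(j)
    .me_number(cs[seq_len(j), seq_len(j), drop = FALSE]), numeric(1))
  p <- min(me_all * ps / me_top)
  .test_result("GATES", NA_real_, NA_real_, min(max(p, 0), 1))
}

#' Cauchy (ACAT) combination of dependent p-values
#'
#' `T = sum_i w_i tan((0.5 - p_i) pi) / sum_i w_i`;
#' `p = 0.5 - arctan(T)/pi`. Valid under arbitrary dependence; inputs are
#' clipped to \[1e-15, 1 - 1e-15\]. NAs are dropped.
#'
#' @param p_values Vector of p-values.
#' @param weights Nonnegative weights (default equal).
#' @return Combined p-value.
#' @export
cauchy_combine <- function(p_values, weights = NULL) {
  ok <- !is.na(p_values)
  p_values <- p_values[ok]
  if (length(p_values) == 0L) stop("no p-values to combine")
  if (is.null(weights)) weights <- rep(1, length(p_values))
  else weights <- weights[ok]
  stopifnot(length(weights) == length(p_values), all(weights >= 0))
  p_values <- pmin(pmax(p_values, 1e-15), 1 - 1e-15)
  Tc <- sum(weights * tan((0.5 - p_values) * pi)) / sum(weights)
  min(max(0.5 - atan(Tc) / pi, 0), 1)
}
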