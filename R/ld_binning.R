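#' Assign variants to LD bins by clique extraction on the r-squared graph
#'
#' Builds a graph on the analyzed variants with an edge between i and j when
#' `corr[i,j]^2 >= r2_bin`, then repeatedly removes the largest maximal
#' clique as a bin until no edges remain; leftover isolated vertices become
#' singleton bins. Ties among equal-size largest cliques are broken by the
#' lexicographically smallest sorted member-index tuple, so the binning is
#' deterministic. Bins are numbered 1..B by decreasing size, then smallest
#' member index.
#'
#' @param corr m x m Pearson correlation matrix of dosages.
#' @param r2_bin Squared-correlation edge threshold in (0,1) (default 0.5,
#'   the usual clique-binning convention for common variants).
#' @return List of class `ld_bins` with `bin_of` (integer vector, bin id per
#'   variant), `sign_of` (all `+1` until [recode_bins_positive()]), `n_bins`,
#'   and `members` (list of member-index vectors per bin).
#' @export
clique_bins <- function(corr, r2_bin = 0.5) {
  stopifnot(r2_bin > 0, r2_bin < 1)
  m <- nrow(corr)
  if (is.null(m) || m == 0L) stop("empty correlation matrix")
  adj <- (corr^2 >= r2_bin)
  diag(adj) <- FALSE
  remaining <- seq_len(m)
  bins <- list()
  while (length(remaining) > 0L) {
    sub <- adj[remaining, remaining, drop = FALSE]
    if (!any(sub)) {
      bins <- c(bins, as.list(remaining))
      break
    }
    g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
    cl <- igraph::max_cliques(g)
    sizes <- lengths(cl)
    cand <- cl[sizes == max(sizes)]
    keys <- lapply(cand, function(v) sort(remaining[as.integer(v)]))
    best <- keys[[.lex_smallest(keys)]]
    bins[[length(bins) + 1L]] <- best
    remaining <- setdiff(remaining, best)
  }
  sizes <- lengths(bins)
  mins <- vapply(bins, min, integer(1))
  ord <- order(-sizes, mins)
  bins <- bins[ord]
  bin_of <- integer(m)
  for (b in seq_along(bins)) bin_of[bins[[b]]] <- b
  structure(list(bin_of = bin_of, sign_of = rep(1L, m),
                 n_bins = length(bins), members = bins),
            class = "ld_bins")
}

# index of the lexicographically smallest integer vector in a list
.lex_smallest <- function(keys) {
  best <- 1L
  for (i in seq_along(keys)[-1]) {
    a <- keys[[i]]; b <- keys[[best]]
    n <- min(length(a), length(b))
    cmp <- 0L
    for (k in seq_len(n)) {
      if (a[k] != b[k]) { cmp <- if (a[k] < b[k]) -1L else 1L; break }
    }
    if (cmp == 0L && length(a) != length(b))
      cmp <- if (length(a) < length(b)) -1L else 1L
    if (cmp < 0L) best <- i
  }
  best
}

#' Recode dosages so within-bin correlations are positive
#'
#' Within each bin, the lowest-index variant anchors sign `+1`; every other
#' member's sign is the sign of its correlation with the anchor, and columns
#' with sign `-1` are replaced by `2 - dosage`. A zero correlation with the
#' anchor keeps sign `+1` with a warning. The flip flags compose with any
#' earlier minor-allele flip.
#'
#' @param block A filtered `genotype_block` the bins were computed on.
#' @param bins An `ld_bins` assignment.
#' @return List with the recoded `block` and updated `bins` (with `sign_of`
#'   filled in).
#' @export
recode_bins_positive <- function(block, bins) {
  corr <- pairwise_correlation(block)
  sign_of <- rep(1L, ncol(block$dosage))
  for (mem in bins$members) {
    if (length(mem) < 2L) next
    anchor <- min(mem)
    for (j in setdiff(mem, anchor)) {
      r <- corr[anchor, j]
      if (r == 0) {
        warning("zero correlation with bin anchor for variant ",
                block$variants$variant_id[j], "; sign +1 kept")
        next
      }
      if (r < 0) sign_of[j] <- -1L
    }
  }
  flip <- sign_of == -1L
  if (any(flip)) {
    block$dosage[, flip] <- 2 - block$dosage[, flip, drop = FALSE]
    block$variants$flipped_to_minor[flip] <- !block$variants$flipped_to_minor[flip]
  }
  bins$sign_of <- sign_of
  list(block = block, bins = bins)
}

#' MLC contrast matrix from an LD-bin assignment
#'
#' Row b of W averages the coefficients of bin b's members:
#' `W[b, j] = sign_of(j) / |bin b|` for members, 0 elsewhere. When the block
#' has already been sign-recoded by [recode_bins_positive()] pass
#' `signs_absorbed = TRUE` so all weights are positive.
#'
#' @param bins An `ld_bins` assignment.
#' @param m Number of variants (columns of W).
#' @param signs_absorbed Logical; `TRUE` when the dosage block already holds
#'   the recoded columns.
#' @return B x m contrast matrix, rows in bin order.
#' @export
bin_contrast_matrix <- function(bins, m, signs_absorbed = TRUE) {
  W <- matrix(0, bins$n_bins, m)
  for (b in seq_len(bins$n_bins)) {
    mem <- bins$members[[b]]
    w <- 1 / length(mem)
    W[b, mem] <- if (signs_absorbed) w else bins$sign_of[mem] * w
  }
  W
}
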