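# Independent oracles and fixture builders used across the suite.

# Bron--Kerbosch enumeration of all maximal cliques of an adjacency matrix.
# Written independently of the package's clique machinery.
bk_max_cliques <- function(adj) {
  n <- nrow(adj)
  out <- list()
  bk <- function(R, P, X) {
    if (!length(P) && !length(X)) {
      out[[length(out) + 1L]] <<- sort(R)
      return(invisible())
    }
    for (v in P) {
      nb <- which(adj[v, ])
      bk(c(R, v), intersect(P, nb), intersect(X, nb))
      P <- setdiff(P, v)
      X <- c(X, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  out
}

# Greedy largest-clique extraction with lexicographic tie-breaking, built on
# the brute-force enumerator: the reference binning for small graphs.
oracle_greedy_bins <- function(adj) {
  n <- nrow(adj)
  remaining <- seq_len(n)
  bins <- list()
  repeat {
    if (!length(remaining)) break
    sub <- adj[remaining, remaining, drop = FALSE]
    if (!any(sub)) {
      bins <- c(bins, as.list(remaining))
      break
    }
    cl <- bk_max_cliques(sub)
    cl <- lapply(cl, function(v) sort(remaining[v]))
    sizes <- lengths(cl)
    cl <- cl[sizes == max(sizes)]
    keys <- vapply(cl, function(v) paste(sprintf("%04d", v), collapse = ","),
                   character(1))
    best <- cl[[which.min(rank(keys, ties.method = "first"))]]
    bins[[length(bins) + 1L]] <- best
    remaining <- setdiff(remaining, best)
  }
  sizes <- lengths(bins)
  mins <- vapply(bins, min, numeric(1))
  bins[order(-sizes, mins)]
}

# A small standard fixture: block-LD genotypes plus a null or causal
# phenotype, reused by the pipeline tests.
make_fixture <- function(dir, n = 200, seed = 11, causal = c(rs2 = 0.4),
                         family = "gaussian", with_ds = FALSE,
                         add_multiallelic = FALSE) {
  blk <- simulate_genotypes(
    n, mafs = rep(c(0.1, 0.2, 0.3, 0.4), 3),
    blocks = list(list(idx = 1:4, rho = 0.8), list(idx = 5:8, rho = 0.5)),
    seed = seed)
  regions <- data.frame(region_id = c("1", "2"), chrom = "1",
                        start = c(1L, 6001L), end = c(6000L, 12000L),
                        stringsAsFactors = FALSE)
  class(regions) <- c("region_def", "data.frame")
  y <- simulate_phenotype(blk, causal = causal, family = family,
                          seed = seed + 1)
  paths <- write_fixture(blk, regions, y, prefix = file.path(dir, "fix"),
                         with_ds = with_ds,
                         add_multiallelic = add_multiallelic, seed = seed)
  list(block = blk, regions = regions, y = y, paths = paths)
}
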