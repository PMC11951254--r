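corr_from_edges <- function(m, edges, r_in = 0.9, r_out = 0.1) {
  corr <- matrix(r_out, m, m)
  diag(corr) <- 1
  for (e in edges) {
    corr[e[1], e[2]] <- r_in
    corr[e[2], e[1]] <- r_in
  }
  corr
}

test_that("clique binning covers complete, empty and path graphs", {
  # complete graph on 3 -> one bin
  b1 <- clique_bins(corr_from_edges(3, list(c(1,2), c(1,3), c(2,3))), 0.5)
  expect_equal(b1$n_bins, 1L)
  expect_equal(b1$bin_of, rep(1L, 3))
  # no edges -> singletons
  b2 <- clique_bins(corr_from_edges(4, list()), 0.5)
  expect_equal(b2$n_bins, 4L)
  # path 1-2-3: tie between {1,2} and {2,3} broken lexicographically
  b3 <- clique_bins(corr_from_edges(3, list(c(1,2), c(2,3))), 0.5)
  expect_equal(b3$members, list(c(1L, 2L), 3L))
  expect_error(clique_bins(matrix(numeric(), 0, 0), 0.5), "empty")
})

test_that("bins partition the variant set and match the brute-force oracle", {
  for (s in 1:40) {
    set.seed(s)
    m <- sample(2:8, 1)
    adj <- matrix(runif(m * m) < 0.4, m, m)
    adj <- adj | t(adj); diag(adj) <- FALSE
    corr <- matrix(0.1, m, m); diag(corr) <- 1
    corr[adj] <- 0.9
    bins <- clique_bins(corr, 0.5)
    expect_equal(sort(unlist(bins$members)), 1:m)
    expect_equal(bins$members, oracle_greedy_bins(adj))
  }
})

test_that("positive recoding flips signs without changing |r|", {
  set.seed(3)
  n <- 500
  base <- rbinom(n, 2, 0.4)
  noisy <- function(g) pmin(pmax(g + sample(c(-1, 0, 1), n, TRUE,
                                            c(0.1, 0.8, 0.1)), 0), 2)
  d <- cbind(base, 2 - noisy(base), noisy(base))
  colnames(d) <- paste0("v", 1:3)
  blk <- structure(list(samples = as.character(1:n), dosage = d,
                        variants = data.frame(
                          variant_id = colnames(d), chrom = "1",
                          pos = c(10L, 20L, 30L), ref = "A", alt = "G",
                          maf = colMeans(d) / 2, source_multiallelic = FALSE,
                          flipped_to_minor = FALSE, stringsAsFactors = FALSE),
                        missingness = rep(0, 3)), class = "genotype_block")
  r0 <- pairwise_correlation(blk)
  bins <- clique_bins(r0, 0.5)
  expect_equal(bins$n_bins, 1L)
  rec <- recode_bins_positive(blk, bins)
  expect_equal(rec$bins$sign_of, c(1L, -1L, 1L))
  r1 <- pairwise_correlation(rec$block)
  expect_true(all(r1[upper.tri(r1)] >= 0))
  expect_equal(abs(r1), abs(r0), tolerance = 1e-12, ignore_attr = TRUE)
  # recoded flip composes with the minor-allele flag
  expect_true(rec$block$variants$flipped_to_minor[2])
  # singleton bins are untouched
  b2 <- clique_bins(diag(3) + 0, 0.5)
  rec2 <- recode_bins_positive(blk, b2)
  expect_equal(rec2$block$dosage, blk$dosage)
})

test_that("recoded signs maximize the sum of pairwise correlations", {
  # anchor correlations (+0.8, -0.7): exhaustive check over sign patterns
  set.seed(9)
  n <- 2000
  z <- rnorm(n)
  g1 <- (z + rnorm(n, sd = 0.6) > 0) + (z + rnorm(n, sd = 0.6) > 0.8)
  g2 <- (z + rnorm(n, sd = 0.9) > 0) + (z + rnorm(n, sd = 0.9) > 0.8)
  g3 <- 2 - ((z + rnorm(n, sd = 1.1) > 0) + (z + rnorm(n, sd = 1.1) > 0.8))
  d <- cbind(g1, g2, g3); colnames(d) <- paste0("v", 1:3)
  blk <- structure(list(samples = as.character(1:n), dosage = d,
                        variants = data.frame(
                          variant_id = colnames(d), chrom = "1",
                          pos = c(1L, 2L, 3L), ref = "A", alt = "G",
                          maf = colMeans(d) / 2, source_multiallelic = FALSE,
                          flipped_to_minor = FALSE, stringsAsFactors = FALSE),
                        missingness = rep(0, 3)), class = "genotype_block")
  r0 <- pairwise_correlation(blk)
  expect_gt(r0[1, 2], 0); expect_lt(r0[1, 3], 0)
  bins <- structure(list(bin_of = rep(1L, 3), sign_of = rep(1L, 3),
                         n_bins = 1L, members = list(1:3)),
                    class = "ld_bins")
  rec <- recode_bins_positive(blk, bins)
  signs <- rec$bins$sign_of
  score <- function(s) sum((outer(s, s) * r0)[upper.tri(r0)])
  best <- max(apply(expand.grid(1, c(-1, 1), c(-1, 1)), 1, score))
  expect_equal(score(signs), best)
  r1 <- pairwise_correlation(rec$block)
  expect_true(all(r1[upper.tri(r1)] >= 0))
})

test_that("contrast matrix encodes bin averages", {
  b <- structure(list(bin_of = c(1L, 1L, 2L), sign_of = c(1L, 1L, 1L),
                      n_bins = 2L, members = list(c(1L, 2L), 3L)),
                 class = "ld_bins")
  expect_equal(bin_contrast_matrix(b, 3),
               rbind(c(0.5, 0.5, 0), c(0, 0, 1)))
  singles <- structure(list(bin_of = 1:3, sign_of = rep(1L, 3), n_bins = 3L,
                            members = list(1L, 2L, 3L)), class = "ld_bins")
  expect_equal(bin_contrast_matrix(singles, 3), diag(3))
  one <- structure(list(bin_of = rep(1L, 3), sign_of = c(1L, -1L, 1L),
                        n_bins = 1L, members = list(1:3)), class = "ld_bins")
  expect_equal(bin_contrast_matrix(one, 3, signs_absorbed = FALSE),
               matrix(c(1, -1, 1) / 3, 1))
})
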