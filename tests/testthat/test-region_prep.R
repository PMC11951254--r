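test_that("MAF computation and flip flag follow the minor-allele rule", {
  expect_equal(compute_maf(c(0, 1, 2, 1)), list(maf = 0.5, flip = FALSE))
  expect_equal(compute_maf(c(2, 2, 2, 2)), list(maf = 0, flip = TRUE))
  expect_equal(compute_maf(c(0, 0, 0, 1)), list(maf = 0.125, flip = FALSE))
  expect_error(compute_maf(c(0, 3)), "outside")
  expect_error(compute_maf(numeric(0)), "empty")
})

make_block <- function(dosage, miss = rep(0, ncol(dosage))) {
  m <- ncol(dosage)
  structure(list(samples = as.character(seq_len(nrow(dosage))),
                 dosage = dosage,
                 variants = data.frame(
                   variant_id = paste0("v", seq_len(m)), chrom = "1",
                   pos = seq_len(m) * 10L, ref = "A", alt = "G",
                   maf = NA_real_, source_multiallelic = FALSE,
                   flipped_to_minor = FALSE, stringsAsFactors = FALSE),
                 missingness = miss), class = "genotype_block")
}

test_that("variant filtering prunes with reasons and recodes to minor allele", {
  d <- cbind(rep(2, 10),                  # monomorphic (after flip, maf 0)
             c(1, rep(0, 9)),             # maf 0.05
             c(rep(2, 7), 1, 1, 0))       # alt-major: f 0.8, maf 0.2
  blk <- make_block(d)
  fl <- filter_variants(blk, maf_min = 0.05, region_id = "r")
  expect_equal(fl$prune_log$reason, "MONOMORPHIC")
  expect_equal(ncol(fl$block$dosage), 2L)    # maf == maf_min kept (inclusive)
  expect_equal(fl$block$variants$maf, c(0.05, 0.2))
  # flipped column now counts the minor allele
  expect_true(fl$block$variants$flipped_to_minor[2])
  expect_equal(unname(fl$block$dosage[, 2]), 2 - d[, 3])
  expect_true(all(colMeans(fl$block$dosage) / 2 <= 0.5))

  fl2 <- filter_variants(make_block(d), maf_min = 0.2, region_id = "r")
  expect_setequal(fl2$prune_log$reason, c("MONOMORPHIC", "MAF_BELOW_MIN"))
  expect_equal(ncol(fl2$block$dosage), 0L)

  # missingness gate
  blk3 <- make_block(d[, 2:3], miss = c(0.2, 0))
  fl3 <- filter_variants(blk3, maf_min = 0.01, miss_max = 0.05)
  expect_equal(fl3$prune_log$reason, "MISSINGNESS_ABOVE_MAX")
})

test_that("pairwise correlation matches direct computation", {
  set.seed(5)
  d <- matrix(sample(0:2, 18, TRUE), 6, 3)
  while (any(apply(d, 2, var) == 0)) d <- matrix(sample(0:2, 18, TRUE), 6, 3)
  blk <- make_block(d)
  r <- pairwise_correlation(blk)
  expect_equal(r, cor(d), ignore_attr = TRUE)
  expect_equal(diag(r), rep(1, 3), ignore_attr = TRUE)
  d2 <- cbind(d[, 1], d[, 1], 2 - d[, 1])
  r2 <- pairwise_correlation(make_block(d2))
  expect_equal(r2[1, 2], 1)
  expect_equal(r2[1, 3], -1)
})

test_that("greedy LD pruning scans in position order and is idempotent", {
  # chain: r2(1,2)=r2(2,3)=0.99, r2(1,3)=0.5
  corr <- diag(3)
  corr[1, 2] <- corr[2, 1] <- sqrt(0.99)
  corr[2, 3] <- corr[3, 2] <- sqrt(0.99)
  corr[1, 3] <- corr[3, 1] <- sqrt(0.5)
  vars <- data.frame(variant_id = c("a", "b", "c"), pos = c(10L, 20L, 30L))
  pr <- ld_prune(corr, vars, 0.98)
  expect_equal(pr$keep, c(1L, 3L))
  expect_equal(pr$prune_log$variant_id, "b")
  expect_equal(pr$prune_log$reason, "LD_PRUNED")
  # idempotence on the kept subset
  pr2 <- ld_prune(corr[pr$keep, pr$keep], vars[pr$keep, ], 0.98)
  expect_equal(pr2$keep, c(1L, 2L))
  expect_equal(nrow(pr2$prune_log), 0L)
  # identical pair: first in position order kept
  c2 <- matrix(c(1, 1, 1, 1), 2)
  pr3 <- ld_prune(c2, data.frame(variant_id = c("x", "y"),
                                 pos = c(5L, 6L)), 0.98)
  expect_equal(pr3$keep, 1L)
  # orthogonal variants all kept
  pr4 <- ld_prune(diag(3), vars, 0.98)
  expect_equal(pr4$keep, 1:3)
})

test_that("VIF equals the regression-R2 closed form", {
  set.seed(7)
  n <- 200
  z <- rnorm(n)
  g1 <- pmin(pmax(round(z + rnorm(n, sd = 0.5) + 1), 0), 2)
  g2 <- pmin(pmax(round(z + rnorm(n, sd = 0.5) + 1), 0), 2)
  blk <- make_block(cbind(g1, g2))
  r <- cor(g1, g2)
  expect_equal(compute_vif(blk), rep(1 / (1 - r^2), 2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(compute_vif(make_block(cbind(g1))), 1)
  # oracle: regression of each column on the others, random 5-variant blocks
  for (s in 1:5) {
    set.seed(100 + s)
    G <- matrix(sample(0:2, 5 * 60, TRUE), 60, 5)
    while (any(apply(G, 2, var) == 0))
      G <- matrix(sample(0:2, 5 * 60, TRUE), 60, 5)
    v <- compute_vif(make_block(G))
    for (j in 1:5) {
      r2 <- summary(lm(G[, j] ~ G[, -j]))$r.squared
      expect_equal(v[j], 1 / (1 - r2), tolerance = 1e-8)
    }
    expect_true(all(v >= 1 - 1e-8))
  }
})
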