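test_that("chi-square mixture tail agrees with single-term and Liu fallback", {
  expect_equal(pchisum(3.84, 1), pchisq(3.84, 1, lower.tail = FALSE))
  expect_equal(pchisum(7, c(2, 2)), pchisq(3.5, 2, lower.tail = FALSE),
               tolerance = 1e-4)
  lam <- c(4, 2, 1, 0.5)
  q <- 12
  expect_equal(pchisum(q, lam, "imhof"), pchisum(q, lam, "liu"),
               tolerance = 0.01)
})

test_that("SKAT reduces to the score test at m=1 and is sane on toy data", {
  set.seed(12)
  n <- 300
  g <- matrix(rbinom(n, 2, 0.3), ncol = 1)
  y <- rnorm(n)
  sk <- skat_test(y, g, NULL, "gaussian")
  # 1-eigenvalue mixture is a scaled 1-df chi-square = the score test
  r <- y - mean(y)
  s2 <- sum(r^2) / (n - 1)
  u <- sum(g * r) / s2
  v <- sum((g - mean(g))^2) / s2
  expect_equal(sk$p, pchisq(u^2 / v, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_error(skat_test(y, g, NULL, "gaussian", weights = 0), "zero")
})

test_that("SKAT p agrees with a large-sample Monte-Carlo mixture oracle", {
  blk <- simulate_genotypes(200, mafs = c(0.1, 0.2, 0.3, 0.4, 0.25),
                            blocks = list(list(idx = 1:3, rho = 0.6)),
                            seed = 31)
  G <- blk$dosage
  set.seed(32)
  y <- rnorm(200)
  sk <- skat_test(y, G, NULL, "gaussian")
  # oracle: eigenvalues from an independent projection, 1e6 mixture draws
  r <- resid(lm(y ~ 1))
  s2 <- sum(r^2) / (200 - 1)
  Gc <- scale(G, center = TRUE, scale = FALSE)
  lam <- eigen(crossprod(Gc), symmetric = TRUE)$values
  Q <- sum(drop(crossprod(G, r))^2) / s2
  set.seed(33)
  draws <- colSums(lam * matrix(rchisq(length(lam) * 1e6, df = 1),
                                length(lam)))
  p_mc <- mean(draws > Q)
  se_mc <- sqrt(p_mc * (1 - p_mc) / 1e6)
  expect_lt(abs(sk$p - p_mc), 2 * se_mc + 1e-12)
})

test_that("SKAT-O endpoints recover SKAT and the burden score test", {
  blk <- simulate_genotypes(250, mafs = rep(c(0.15, 0.3), 3),
                            blocks = list(list(idx = 1:3, rho = 0.5)),
                            seed = 41)
  G <- blk$dosage
  set.seed(42)
  y <- rnorm(250)
  expect_equal(skat_o_test(y, G, NULL, "gaussian", rho_grid = 0)$p,
               skat_test(y, G, NULL, "gaussian")$p, tolerance = 1e-10)
  b <- skat_o_test(y, G, NULL, "gaussian", rho_grid = 1)$p
  burden <- skat_test(y, as.matrix(rowSums(G)), NULL, "gaussian")$p
  expect_equal(b, burden, tolerance = 1e-10)
  # full grid: p between min and Bonferroni bound of the per-rho p-values
  full <- skat_o_test(y, G, NULL, "gaussian")
  expect_gte(full$p, 0); expect_lte(full$p, 1)
  # m=1 collapses to SKAT
  g1 <- G[, 1, drop = FALSE]
  expect_equal(skat_o_test(y, g1, NULL, "gaussian")$p,
               skat_test(y, g1, NULL, "gaussian")$p, tolerance = 1e-12)
})

test_that("binomial SKAT keeps type-I error near nominal on a small null", {
  set.seed(55)
  rej <- 0L
  nrep <- 200L
  for (r in 1:nrep) {
    blk <- simulate_genotypes(250, mafs = rep(0.3, 5),
                              blocks = list(list(idx = 1:5, rho = 0.4)),
                              seed = 7000 + r)
    y <- rbinom(250, 1, 0.3)
    p <- skat_test(y, blk$dosage, NULL, "binomial")$p
    if (p < 0.05) rej <- rej + 1L
  }
  ci <- qbinom(c(0.005, 0.995), nrep, 0.05)
  expect_gte(rej, ci[1]); expect_lte(rej, ci[2])
})
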