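test_that("joint gaussian fit matches the closed-form least squares", {
  y <- c(1, 2, 3, 4)
  g <- matrix(c(0, 1, 1, 2), 4, 1)
  fit <- fit_joint(y, g, NULL, "gaussian")
  expect_equal(fit$beta_hat, 1.5)
  expect_equal(sqrt(fit$cov_hat[1, 1]), sqrt(0.25 / 2), tolerance = 1e-6)
  expect_equal(fit$residual_df, 2L)
  # same numbers from the marginal single-variant path
  sv <- single_variant_tests(y, g, NULL, "gaussian")
  expect_equal(sv$beta, 1.5)
  expect_equal(sv$se, 0.35355, tolerance = 1e-4)
  # m = 0: covariate-only fit
  fit0 <- fit_joint(y, NULL, NULL, "gaussian")
  expect_length(fit0$beta_hat, 0L)
  # rank deficiency is a hard error pointing at pruning
  expect_error(fit_joint(rnorm(10), cbind(g2 <- rbinom(10, 2, .4), g2)),
               "RANK_DEFICIENT")
})

test_that("Firth penalization matches the Jeffreys closed form and the MLE limit", {
  # intercept-only, 0 of 10: fitted probability (0 + 1/2)/(10 + 1)
  f0 <- firth_logistic(rep(0, 10), matrix(1, 10, 1))
  expect_true(f0$converged)
  expect_equal(unique(round(f0$fitted, 10)), round(0.5 / 11, 10))
  f5 <- firth_logistic(c(rep(1, 5), rep(0, 5)), matrix(1, 10, 1))
  expect_equal(unique(round(f5$fitted, 10)), 0.5)
  # penalty vanishes at large n: within 10% of the unpenalized MLE
  set.seed(21)
  n <- 1000
  g <- rbinom(n, 2, 0.3)
  y <- rbinom(n, 1, plogis(-0.5 + 0.6 * g))
  X <- cbind(1, g)
  ff <- firth_logistic(y, X)
  ml <- glm(y ~ g, family = binomial())
  expect_equal(unname(ff$coefficients), unname(coef(ml)), tolerance = 0.1)
  # complete separation still yields finite estimates via fit_joint
  ys <- c(rep(0, 20), rep(1, 20))
  gs <- matrix(c(rep(0, 20), rep(2, 20)), ncol = 1)
  fits <- fit_joint(ys, gs, NULL, "binomial", firth = TRUE)
  expect_true(fits$converged)
  expect_true(all(is.finite(fits$beta_hat)))
})

test_that("Wald region test reduces to t-test at m=1 and handles beta=0", {
  set.seed(2)
  n <- 80
  g <- matrix(rbinom(n, 2, 0.3), ncol = 1)
  y <- rnorm(n)
  fit <- fit_joint(y, g, NULL, "gaussian")
  w <- wald_region_test(fit)
  tt <- summary(lm(y ~ g))$coefficients[2, 4]
  expect_equal(w$p, tt, tolerance = 1e-10)
  # beta = 0 vector gives T = 0, p = 1
  fit$beta_hat <- rep(0, 1)
  expect_equal(wald_region_test(fit)$p, 1)
  # m=2 toy matches explicit 2x2 inversion
  g2 <- cbind(g, rbinom(n, 2, 0.4))
  fit2 <- fit_joint(y, g2, NULL, "gaussian")
  Tq <- drop(t(fit2$beta_hat) %*% solve(fit2$cov_hat) %*% fit2$beta_hat)
  w2 <- wald_region_test(fit2)
  expect_equal(w2$stat, Tq / 2, tolerance = 1e-10)
  expect_equal(w2$p, pf(Tq / 2, 2, n - 3, lower.tail = FALSE))
})

test_that("MLC reductions: identity contrasts give Wald, B=1 gives LC, row scaling is free", {
  set.seed(4)
  n <- 150
  G <- sapply(1:4, function(i) rbinom(n, 2, 0.3))
  y <- rnorm(n)
  fit <- fit_joint(y, G, NULL, "gaussian")
  w <- wald_region_test(fit)
  mI <- mlc_test(fit, diag(4))
  expect_equal(mI$region$stat, w$stat, tolerance = 1e-10)
  expect_equal(mI$region$p, w$p, tolerance = 1e-10)
  W1 <- matrix(1 / 4, 1, 4)
  expect_equal(mlc_test(fit, W1)$region$p, lc_test(fit)$p, tolerance = 1e-12)
  # invariance to positive row rescaling
  W <- rbind(c(0.5, 0.5, 0, 0), c(0, 0, 0.5, 0.5))
  W2 <- W; W2[1, ] <- 2 * W2[1, ]
  expect_equal(mlc_test(fit, W)$region$stat, mlc_test(fit, W2)$region$stat,
               tolerance = 1e-12)
  # bin-level results satisfy stat = (estimate/se)^2
  mb <- mlc_test(fit, W)
  expect_equal(mb$bins$stat, (mb$bins$estimate / mb$bins$se)^2,
               tolerance = 1e-12)
})

test_that("LC beats Wald under a burden-favorable architecture", {
  set.seed(77)
  wins <- 0L
  for (r in 1:200) {
    blk <- simulate_genotypes(300, mafs = rep(0.3, 5),
                              blocks = list(list(idx = 1:5, rho = 0.3)),
                              seed = 5000 + r)
    G <- blk$dosage
    y <- drop(G %*% rep(0.12, 5)) + rnorm(300)
    fit <- fit_joint(y, G, NULL, "gaussian")
    if (lc_test(fit)$p <= wald_region_test(fit)$p) wins <- wins + 1L
  }
  expect_gte(wins, 160L)
})

test_that("PC80 picks the documented component counts", {
  set.seed(6)
  n <- 400
  # independent variants: equal eigenvalues, k = 4 of 5 at 0.8
  G5 <- sapply(1:5, function(i) rbinom(n, 2, 0.4))
  y <- rnorm(n)
  expect_equal(pc80_test(y, G5, NULL, "gaussian", 0.8)$df, 4)
  # r = 0.95 pair: first eigenvalue 1.95/2 >= 0.8 so k = 1
  corr_target <- 0.95
  z <- rnorm(n)
  repeat {
    g1 <- (z + rnorm(n, sd = 0.18) > 0.3) + (z + rnorm(n, sd = 0.18) > 1)
    g2 <- (z + rnorm(n, sd = 0.18) > 0.3) + (z + rnorm(n, sd = 0.18) > 1)
    if (cor(g1, g2) >= 0.9) break
  }
  p2 <- pc80_test(y, cbind(g1, g2), NULL, "gaussian", 0.8)
  expect_equal(p2$df, 1)
  # m = 1 equals the single-variant test
  p1 <- pc80_test(y, G5[, 1, drop = FALSE], NULL, "gaussian")
  sv <- single_variant_tests(y, G5[, 1, drop = FALSE], NULL, "gaussian")
  expect_equal(p1$p, sv$p, tolerance = 1e-10)
})

test_that("simpleM follows its closed forms", {
  p <- c(0.01, runif(9, 0.2, 0.9))
  sm <- simple_m(diag(10), p)
  expect_equal(sm$df, 10)
  expect_equal(sm$p, 1 - 0.99^10, tolerance = 1e-12)
  all1 <- matrix(1, 10, 10)
  expect_equal(simple_m(all1, p)$p, min(p), tolerance = 1e-12)
  expect_equal(simple_m(all1, p)$df, 1)
  expect_equal(simple_m(matrix(1, 1, 1), 0.3)$p, 0.3)
  # M_eff always in [1, m]
  for (s in 1:10) {
    set.seed(s)
    G <- matrix(rbinom(50 * 6, 2, 0.3), 50, 6)
    while (any(apply(G, 2, var) == 0))
      G <- matrix(rbinom(50 * 6, 2, 0.3), 50, 6)
    df <- simple_m(cor(G), runif(6))$df
    expect_gte(df, 1); expect_lte(df, 6)
  }
})

test_that("GATES reduces to Simes under independence and min p under perfect LD", {
  p <- c(0.01, 0.02, 0.03)
  expect_equal(gates(diag(3), p)$p, 0.03, tolerance = 1e-12)
  expect_equal(gates(matrix(1, 1, 1), 0.2)$p, 0.2)
  expect_equal(gates(matrix(1, 3, 3), p)$p, 0.01, tolerance = 1e-12)
  # never exceeds the Bonferroni-corrected min p by more than Me rounding
  for (s in 1:10) {
    set.seed(s)
    G <- matrix(rbinom(80 * 5, 2, 0.3), 80, 5)
    while (any(apply(G, 2, var) == 0))
      G <- matrix(rbinom(80 * 5, 2, 0.3), 80, 5)
    pv <- runif(5)
    expect_lte(gates(cor(G), pv)$p, min(pv) * 5 + 1e-12)
  }
})

test_that("Cauchy combination is an identity, symmetric, and handles extremes", {
  expect_equal(cauchy_combine(0.37), 0.37, tolerance = 1e-12)
  expect_equal(cauchy_combine(c(0.5, 0.5)), 0.5, tolerance = 1e-12)
  expect_equal(cauchy_combine(c(0.01, 0.99)), 0.5, tolerance = 1e-10)
  expect_error(cauchy_combine(numeric(0)), "no p-values")
  expect_lt(cauchy_combine(c(1e-20, 0.5)), 1e-10)  # clipping keeps it finite
})
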