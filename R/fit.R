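#' Joint multiple-variant regression fit
#'
#' Fits `y ~ intercept + X + G` and returns the variant coefficient vector
#' with its covariance block (covariates profiled out of the report, not the
#' fit). Gaussian traits use least squares with the classical covariance;
#' binary traits use IRLS maximum likelihood ([stats::glm.fit()]) or, with
#' `firth = TRUE` (or on IRLS non-convergence, when Firth is auto-enabled),
#' the Jeffreys-prior penalized fit of [firth_logistic()].
#'
#' @param y Response vector.
#' @param G n x m dosage matrix (recoded); m may be 0.
#' @param X n x c covariate matrix (c may be 0); an intercept is always added.
#' @param family `"gaussian"` or `"binomial"`.
#' @param firth Use Firth penalization for binomial fits.
#' @return A `joint_fit`: list with `beta_hat`, `cov_hat`, `family`, `n`,
#'   `residual_df`, `converged`, `sigma2` (gaussian), and the full-design
#'   `all_beta`/`all_cov`/`term_names` for covariate reporting.
#' @export
fit_joint <- function(y, G, X = NULL, family = c("gaussian", "binomial"),
                      firth = FALSE) {
  family <- match.arg(family)
  n <- length(y)
  G <- if (is.null(G)) matrix(numeric(), n, 0) else as.matrix(G)
  X <- if (is.null(X)) matrix(numeric(), n, 0) else as.matrix(X)
  m <- ncol(G); cc <- ncol(X)
  D <- cbind(`(Intercept)` = 1, X, G)
  if (is.null(colnames(G)) && m > 0)
    colnames(D)[(2 + cc):(1 + cc + m)] <- paste0("g", seq_len(m))
  qrD <- qr(D)
  if (qrD$rank < ncol(D))
    stop("RANK_DEFICIENT: design matrix is rank deficient; ",
         "prune collinear variants first")
  gi <- seq.int(2 + cc, length.out = m)
  if (family == "gaussian") {
    if (n <= m + cc + 1) stop("n must exceed m + c + 1 for a gaussian fit")
    fit <- stats::lm.fit(D, y)
    rdf <- n - m - cc - 1
    sigma2 <- sum(fit$residuals^2) / rdf
    XtXinv <- chol2inv(chol(crossprod(D)))
    all_cov <- sigma2 * XtXinv
    res <- list(beta_hat = unname(fit$coefficients[gi]),
                cov_hat = all_cov[gi, gi, drop = FALSE],
                family = family, n = n, residual_df = rdf,
                converged = TRUE, sigma2 = sigma2,
                all_beta = fit$coefficients, all_cov = all_cov,
                term_names = colnames(D))
  } else {
    if (firth) {
      ff <- firth_logistic(y, D)
      beta <- ff$coefficients; covb <- ff$cov; conv <- ff$converged
    } else {
      gf <- suppressWarnings(
        stats::glm.fit(D, y, family = stats::binomial()))
      conv <- isTRUE(gf$converged) && all(abs(gf$coefficients) < 50)
      if (!conv) {          # auto-enable Firth on non-convergence/separation
        ff <- firth_logistic(y, D)
        beta <- ff$coefficients; covb <- ff$cov; conv <- ff$converged
      } else {
        beta <- gf$coefficients
        w <- gf$weights
        covb <- tryCatch(solve(crossprod(D * sqrt(w))),
                         error = function(e) matrix(NA_real_, ncol(D), ncol(D)))
      }
    }
    names(beta) <- colnames(D)
    res <- list(beta_hat = unname(beta[gi]),
                cov_hat = covb[gi, gi, drop = FALSE],
                family = family, n = n, residual_df = n - m - cc - 1,
                converged = conv, sigma2 = NA_real_,
                all_beta = beta, all_cov = covb, term_names = colnames(D))
  }
  class(res) <- "joint_fit"
  res
}

#' Marginal single-variant association tests
#'
#' Fits `y ~ g_j + X` per variant and reports the Wald estimate, standard
#' error and p-value (t reference for gaussian, normal for binomial). A
#' variant whose fit fails yields an NA row rather than aborting.
#'
#' @inheritParams fit_joint
#' @param G n x m dosage matrix (typically the pre-pruning block).
#' @return data.frame with `variant_id`, `beta`, `se`, `p`.
#' @export
single_variant_tests <- function(y, G, X = NULL,
                                 family = c("gaussian", "binomial"),
                                 firth = FALSE) {
  family <- match.arg(family)
  G <- as.matrix(G)
  ids <- colnames(G)
  if (is.null(ids)) ids <- paste0("g", seq_len(ncol(G)))
  out <- data.frame(variant_id = ids, beta = NA_real_, se = NA_real_,
                    p = NA_real_, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(G))) {
    row <- tryCatch({
      fit <- fit_joint(y, G[, j, drop = FALSE], X, family, firth)
      b <- fit$beta_hat[1]
      se <- sqrt(fit$cov_hat[1, 1])
      p <- if (family == "gaussian")
        2 * stats::pt(abs(b / se), df = fit$residual_df, lower.tail = FALSE)
      else 2 * stats::pnorm(abs(b / se), lower.tail = FALSE)
      if (!fit$converged) c(b, se, NA_real_) else c(b, se, p)
    }, error = function(e) rep(NA_real_, 3))
    out$beta[j] <- row[1]; out$se[j] <- row[2]; out$p[j] <- row[3]
  }
  out
}
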