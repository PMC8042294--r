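#' Fit the weighted GBLUP mixed model for one expression profile
#'
#' Fits `y = X beta + a + e` with `a ~ N(0, G sigma_a^2)` and
#' `e ~ N(0, sigma_e^2 diag(1/w))`, the per-miRNA model of a GBLUP-based
#' eQTL scan: the random effect carries the genomic relationship matrix and
#' the residual is heteroskedastic with voom precision weights. Variance
#' components are estimated by REML, profiling the restricted likelihood over
#' the variance ratio `lambda = sigma_a^2 / sigma_e^2` after rotating the
#' weight-transformed model onto the eigenbasis of
#' `diag(sqrt(w)) G diag(sqrt(w))`; the 1-D profile is maximized by Brent
#' search on `log(lambda)`. The null model (`sigma_a^2 = 0`) is fit alongside
#' and the likelihood-ratio statistic `2 * (loglik_full - loglik_null)`,
#' floored at zero, tests `h^2 = 0`.
#'
#' Heritability is `h^2 = sigma_a^2 / (sigma_a^2 + sigma_e^2)`. Breeding
#' values are `a_hat = sigma_a^2 G V^-1 (y - X beta_hat)` with their BLUP
#' covariance `var(a_hat) = sigma_a^4 G P G`, where `P` is the REML projection
#' `V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1`.
#'
#' @param y Numeric response vector (log-CPM of one miRNA across samples).
#' @param X Fixed-effect design matrix, full column rank.
#' @param G Genomic relationship matrix (samples x samples), or a
#'   [build_grm()] object.
#' @param weights Positive per-sample precision weights (defaults to 1).
#' @param loglambda_interval Search interval for `log(lambda)`.
#' @param compute_se If `TRUE`, a standard error for `h^2` from the curvature
#'   of the profile restricted likelihood is included (NA at the boundary).
#' @param mirna Optional label stored with the fit.
#' @return An object of class `"gblup_fit"` with elements `beta`, `a_hat`,
#'   `var_a_hat`, `sigma2_a`, `sigma2_e`, `h2`, `loglik_full`, `loglik_null`,
#'   `lrt_stat`, `p_h2`, `weights`, `P` (projection matrix), `Py`, plus the
#'   inputs needed by downstream stages.
#' @export
fit_gblup <- function(y, X, G, weights = NULL,
                      loglambda_interval = c(-10, 10),
                      compute_se = FALSE, mirna = NULL) {
  if (inherits(G, "genomic_relationship")) G <- G$G
  y <- as.numeric(y)
  X <- as.matrix(X)
  n <- length(y)
  p <- ncol(X)
  stopifnot(nrow(X) == n, nrow(G) == n, ncol(G) == n)
  if (qr(X)$rank < p) {
    abort("`X` must have full column rank", class = "mireqtl_input_error")
  }
  w <- weights %||% rep(1, n)
  w <- as.numeric(w)
  if (length(w) != n || any(!is.finite(w)) || any(w <= 0)) {
    abort("`weights` must be positive and finite, one per sample",
          class = "mireqtl_input_error")
  }
  # Weights are scale-free (only relative precision matters for the fit);
  # rescale so mean(1/w) = 1, making sigma2_e the average residual variance
  # and h2 a well-defined variance share.
  w <- w * mean(1 / w)

  sw <- sqrt(w)
  ys <- y * sw
  Xs <- X * sw
  Gs <- G * tcrossprod(sw)
  eg <- eigen(Gs, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  yt <- crossprod(eg$vectors, ys)
  Xt <- crossprod(eg$vectors, Xs)
  const <- 0.5 * sum(log(w))

  profile_ll <- function(lambda) {
    v <- lambda * d + 1
    XtVX <- crossprod(Xt, Xt / v)
    beta <- solve(XtVX, crossprod(Xt, yt / v))
    r <- yt - Xt %*% beta
    rss <- sum(r^2 / v)
    s2e <- rss / (n - p)
    ll <- -0.5 * ((n - p) * log(2 * pi * s2e) + sum(log(v)) +
                    determinant(XtVX, logarithm = TRUE)$modulus + (n - p)) + const
    list(ll = as.numeric(ll), beta = beta, s2e = s2e)
  }

  ll_null <- profile_ll(0)
  opt <- optimize(function(ll) profile_ll(exp(ll))$ll,
                  interval = loglambda_interval, maximum = TRUE, tol = 1e-8)
  cand <- c(opt$maximum, loglambda_interval)
  lls <- vapply(cand, function(ll) profile_ll(exp(ll))$ll, numeric(1))
  best <- cand[which.max(lls)]
  lambda <- exp(best)
  full <- profile_ll(lambda)
  converged <- all(is.finite(c(full$ll, ll_null$ll)))

  # a tiny lambda that does not beat the null is the boundary solution
  if (full$ll <= ll_null$ll) {
    lambda <- 0
    full <- ll_null
  }
  sigma2_e <- full$s2e
  sigma2_a <- lambda * sigma2_e
  h2 <- if (sigma2_a + sigma2_e > 0) sigma2_a / (sigma2_a + sigma2_e) else 0
  lrt <- max(0, 2 * (full$ll - ll_null$ll))

  # back to the original scale for BLUP quantities
  v <- lambda * d + 1
  Vinv <- (eg$vectors %*% ((1 / v) * t(eg$vectors))) * tcrossprod(sw) / sigma2_e
  VinvX <- Vinv %*% X
  XtVX <- crossprod(X, VinvX)
  P <- Vinv - VinvX %*% solve(XtVX, t(VinvX))
  beta <- solve(XtVX, crossprod(VinvX, y))
  Py <- P %*% y
  a_hat <- as.numeric(sigma2_a * (G %*% Py))
  GP <- G %*% P
  var_a_hat <- sigma2_a^2 * (GP %*% G)

  se_h2 <- NA_real_
  if (compute_se && lambda > 0 && h2 > 1e-6 && h2 < 1 - 1e-6) {
    f <- function(h) profile_ll(h / (1 - h))$ll
    eps <- min(1e-3, h2 / 2, (1 - h2) / 2)
    d2 <- (f(h2 + eps) - 2 * f(h2) + f(h2 - eps)) / eps^2
    if (is.finite(d2) && d2 < 0) se_h2 <- sqrt(-1 / d2)
  }

  structure(
    list(
      mirna = mirna %||% NA_character_,
      beta = setNames(as.numeric(beta), colnames(X)),
      a_hat = setNames(a_hat, rownames(G)),
      var_a_hat = var_a_hat,
      sigma2_a = sigma2_a, sigma2_e = sigma2_e,
      h2 = h2, se_h2 = se_h2,
      loglik_full = full$ll, loglik_null = ll_null$ll,
      lrt_stat = lrt,
      p_h2 = lrt_pvalue(lrt),
      weights = w, P = P, Py = as.numeric(Py),
      y = y, X = X, G = G,
      n = n, rank_X = p, converged = converged
    ),
    class = "gblup_fit"
  )
}

#' @export
print.gblup_fit <- function(x, ...) {
  cat(sprintf(
    "<gblup_fit%s> n = %d; sigma2_a = %.4g, sigma2_e = %.4g, h2 = %.3f, LRT = %.3f\n",
    if (is.na(x$mirna)) "" else paste0(" ", x$mirna),
    x$n, x$sigma2_a, x$sigma2_e, x$h2, x$lrt_stat))
  invisible(x)
}

#' Broom-style tidiers for GBLUP fits
#'
#' `tidy()` returns the fixed-effect estimates, one row per term; `glance()`
#' returns a one-row model summary (variance components, heritability,
#' restricted log-likelihoods, LRT and its boundary-mixture p-value).
#'
#' @param x A `gblup_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy gblup_fit
#' @export
tidy.gblup_fit <- function(x, ...) {
  tibble(term = names(x$beta), estimate = as.numeric(x$beta))
}

#' @rdname tidy.gblup_fit
#' @method glance gblup_fit
#' @export
glance.gblup_fit <- function(x, ...) {
  tibble(
    mirna = x$mirna, n = x$n,
    sigma2_a = x$sigma2_a, sigma2_e = x$sigma2_e,
    h2 = x$h2, se_h2 = x$se_h2,
    loglik_full = x$loglik_full, loglik_null = x$loglik_null,
    lrt = x$lrt_stat, p = x$p_h2, converged = x$converged
  )
}

#' Fit the GBLUP model for every miRNA of a normalized expression set
#'
#' @param norm A [voom_transform()] result.
#' @param grm A [build_grm()] object (sample order must match the columns of
#'   `norm`).
#' @param design Fixed-effect design matrix; defaults to the design stored in
#'   `norm`.
#' @param compute_se Passed to [fit_gblup()].
#' @return Named list of `gblup_fit` objects, one per miRNA.
#' @export
fit_gblup_all <- function(norm, grm, design = NULL, compute_se = FALSE) {
  stopifnot(inherits(norm, "voom_norm"), inherits(grm, "genomic_relationship"))
  design <- design %||% norm$design
  ids <- rownames(norm$logcpm)
  fits <- lapply(seq_along(ids), function(i) {
    fit_gblup(norm$logcpm[i, ], design, grm$G, weights = norm$weights[i, ],
              compute_se = compute_se, mirna = ids[i])
  })
  setNames(fits, ids)
}

#' Test heritability across miRNAs with FDR control
#'
#' Computes, for each fit, the likelihood-ratio p-value for `h^2 = 0` under a
#' 50:50 mixture of a point mass at zero and chi-square(1) (the boundary-case
#' reference; `null_dist = "chisq1"` gives the plain chi-square), then adjusts
#' across miRNAs by Benjamini-Hochberg (or a Storey-type q-value with
#' `method = "storey"`).
#'
#' @param fits List of `gblup_fit` objects (e.g. from [fit_gblup_all()]).
#' @param fdr Significance threshold on the q-value.
#' @param method Multiple-testing adjustment, `"BH"` or `"storey"`.
#' @param null_dist Null reference for the LRT, `"mixture"` or `"chisq1"`.
#' @return Tibble: `mirna`, `sigma2_a`, `sigma2_e`, `h2`, `se_h2`, `lrt`, `p`,
#'   `q`, `significant`, `converged`.
#' @export
test_heritability <- function(fits, fdr = 0.05, method = c("BH", "storey"),
                              null_dist = c("mixture", "chisq1")) {
  method <- match.arg(method)
  null_dist <- match.arg(null_dist)
  if (inherits(fits, "gblup_fit")) fits <- list(fits)
  tab <- purrr::map_dfr(fits, glance)
  tab$p <- lrt_pvalue(tab$lrt, null_dist)
  tab$q <- adjust_pvalues(tab$p, ifelse(method == "BH", "BH", "storey"))
  tab$significant <- tab$q < fdr
  dplyr::select(tab, "mirna", "sigma2_a", "sigma2_e", "h2", "se_h2",
                "lrt", "p", "q", "significant", "converged")
}
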