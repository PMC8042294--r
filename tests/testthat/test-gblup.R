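test_that("build_grm satisfies its definitional identities", {
  st <- small_study()
  grm <- st$grm
  expect_lt(max(abs(grm$G - tcrossprod(grm$Z))), 1e-10)
  expect_lt(max(abs(grm$G - t(grm$G))), 1e-12)
  expect_gt(min(eigen(grm$G, symmetric = TRUE, only.values = TRUE)$values),
            -1e-8 * sum(diag(grm$G)))
  n <- nrow(grm$G)
  expect_equal(mean(diag(grm$G)), (n - 1) / n, tolerance = 1e-8)

  # duplicate individuals: identical G rows, off-diagonal equals diagonal
  set.seed(1)
  d <- matrix(rbinom(20 * 30, 2, 0.4), 20, 30)
  d[2, ] <- d[1, ]
  g2 <- build_grm(d)
  expect_equal(g2$G[1, ], g2$G[2, ])
  expect_equal(g2$G[1, 2], g2$G[1, 1])
})

test_that("build_grm drops monomorphic markers and errors when all are", {
  set.seed(2)
  d <- matrix(rbinom(10 * 5, 2, 0.5), 10, 5)
  d[, 3] <- 1
  expect_warning(g <- build_grm(d), "monomorphic")
  expect_equal(length(g$marker_ids), 4)
  expect_error(build_grm(matrix(1, 5, 3)), class = "mireqtl_input_error")
})

test_that("mean diagonal of G approaches 1 for many independent markers", {
  cfg <- sim_config(n_samples = 200, n_markers = 2000, n_chromosomes = 4,
                    ld_block_size = 1, n_mirnas = 1, seed = 21)
  g <- simulate_genotypes(cfg)
  grm <- build_grm(g$dosages)
  expect_lt(abs(mean(diag(grm$G)) - 1), 0.05)
})

test_that("equal weights reproduce the unweighted fit", {
  st <- small_study()
  y <- st$norm$logcpm[3, ]
  f0 <- fit_gblup(y, st$design, st$grm$G)
  f1 <- fit_gblup(y, st$design, st$grm$G, weights = rep(2.7, length(y)))
  expect_equal(f1$h2, f0$h2, tolerance = 1e-8)
  expect_equal(f1$beta, f0$beta, tolerance = 1e-8)
  expect_equal(f1$lrt_stat, f0$lrt_stat, tolerance = 1e-6)
})

test_that("h2 is invariant to response scaling; beta scales linearly", {
  st <- small_study()
  y <- st$norm$logcpm[2, ]
  w <- st$norm$weights[2, ]
  f1 <- fit_gblup(y, st$design, st$grm$G, w)
  f2 <- fit_gblup(5 * y, st$design, st$grm$G, w)
  expect_equal(f2$h2, f1$h2, tolerance = 1e-6)
  expect_equal(f2$beta, 5 * f1$beta, tolerance = 1e-6)
  expect_equal(f2$sigma2_a, 25 * f1$sigma2_a, tolerance = 1e-4)
})

test_that("the LRT equals twice the difference of independently recomputed restricted log-likelihoods", {
  st <- small_study()
  for (i in c(1, 5)) {
    y <- st$norm$logcpm[i, ]
    w <- st$norm$weights[i, ]
    fit <- fit_gblup(y, st$design, st$grm$G, w)
    # the fit normalizes weights to mean(1/w) = 1; mirror that for the oracle
    wn <- w * mean(1 / w)
    ll_full <- dense_reml_ll(y, st$design, st$grm$G, wn,
                             fit$sigma2_a, fit$sigma2_e)
    # null variance estimate by weighted least squares, sigma2_a = 0
    Xw <- st$design * sqrt(wn)
    yw <- y * sqrt(wn)
    r0 <- yw - Xw %*% qr.coef(qr(Xw), yw)
    s2e0 <- sum(r0^2) / (length(y) - ncol(st$design))
    ll_null <- dense_reml_ll(y, st$design, st$grm$G, wn, 0, s2e0)
    expect_equal(fit$lrt_stat, max(0, 2 * (ll_full - ll_null)), tolerance = 1e-6)
    expect_equal(fit$loglik_full, ll_full, tolerance = 1e-6)
  }
})

test_that("the profiled REML objective is maximized at the returned estimate", {
  st <- small_study()
  y <- st$norm$logcpm[1, ]
  w <- st$norm$weights[1, ]
  fit <- fit_gblup(y, st$design, st$grm$G, w)
  wn <- w * mean(1 / w)
  ll_hat <- dense_reml_ll(y, st$design, st$grm$G, wn, fit$sigma2_a, fit$sigma2_e)
  for (lam in c(0.01, 0.1, 0.5, 1, 2, 10)) {
    # profile sigma2_e at this lambda by 1-D optimization
    prof <- optimize(function(s2e) {
      dense_reml_ll(y, st$design, st$grm$G, wn, lam * s2e, s2e)
    }, interval = c(1e-6, 10 * var(y)), maximum = TRUE)
    expect_gte(ll_hat + 1e-6, prof$objective)
  }
})

test_that("a null response yields near-zero heritability and LRT", {
  st <- small_study()
  set.seed(30)
  lrts <- replicate(10, {
    y <- as.numeric(st$design %*% c(5, 0.3, 0.1, -0.2, 0.4)) + rnorm(80)
    fit_gblup(y, st$design, st$grm$G)$lrt_stat
  })
  expect_lt(median(lrts), 0.5)
})

test_that("BLUP quantities satisfy their defining equations", {
  st <- small_study()
  y <- st$norm$logcpm[1, ]
  w <- st$norm$weights[1, ]
  fit <- fit_gblup(y, st$design, st$grm$G, w)
  V <- fit$sigma2_a * st$grm$G + fit$sigma2_e * diag(1 / fit$weights)
  Vi <- solve(V)
  beta <- solve(crossprod(st$design, Vi %*% st$design),
                crossprod(st$design, Vi %*% y))
  expect_equal(unname(fit$beta), as.numeric(beta), tolerance = 1e-8)
  a <- fit$sigma2_a * st$grm$G %*% Vi %*% (y - st$design %*% beta)
  expect_equal(unname(fit$a_hat), as.numeric(a), tolerance = 1e-8)
  expect_equal(fit$h2, fit$sigma2_a / (fit$sigma2_a + fit$sigma2_e))
})

test_that("heritability testing: boundary p-values, BH oracle, calibration", {
  expect_equal(mireqtl:::lrt_pvalue(0), 1)
  expect_equal(mireqtl:::lrt_pvalue(c(0, 2.706)),
               c(1, 0.5 * pchisq(2.706, 1, lower.tail = FALSE)))
  expect_equal(mireqtl:::lrt_pvalue(3, "chisq1"),
               pchisq(3, 1, lower.tail = FALSE))

  # BH step-up equals the brute-force oracle
  expect_equal(p.adjust(c(0.01, 0.02, 0.03, 0.5), "BH"),
               c(0.04, 0.04, 0.04, 0.5))
  set.seed(41)
  for (r in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(p.adjust(p, "BH"), brute_bh(p), tolerance = 1e-12)
  }

  # test_heritability output contract
  fits <- small_fits()
  tab <- test_heritability(fits, fdr = 0.05)
  expect_equal(nrow(tab), length(fits))
  expect_true(all(tab$q >= tab$p - 1e-15))
  expect_true(all(tab$h2 >= 0 & tab$h2 <= 1))
  expect_identical(tab$significant, tab$q < 0.05)
  tab_storey <- test_heritability(fits, method = "storey")
  expect_true(all(tab_storey$q <= tab$q + 1e-12))
})

test_that("glance and tidy expose the fit in broom shape", {
  fits <- small_fits()
  g <- glance(fits[[1]])
  expect_s3_class(g, "tbl_df")
  expect_named(g, c("mirna", "n", "sigma2_a", "sigma2_e", "h2", "se_h2",
                    "loglik_full", "loglik_null", "lrt", "p", "converged"))
  td <- tidy(fits[[1]])
  expect_equal(td$term, colnames(small_study()$design))
})
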