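# Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# A small complete study: 80 samples, 200 markers, 12 miRNAs, one planted
# local eQTL, one phenotype with a pQTL at the same marker, coupled genes.
small_study <- function() {
  cached("small_study", {
    cfg <- sim_config(
      n_samples = 80, n_markers = 200, n_chromosomes = 4, ld_block_size = 20,
      n_mirnas = 12, h2_vector = 0.3,
      causal_plan = data.frame(mirna = 1, marker = 30, effect = 1.5,
                               label = "local"),
      n_phenotypes = 2,
      pqtl_plan = data.frame(phenotype = 1, marker = 30, effect = 1),
      n_genes = 6,
      target_plan = data.frame(mirna = c(1, 1), gene = c(1, 2),
                               coupling = c(-0.8, -0.4)),
      seed = 421
    )
    sim <- simulate_eqtl_study(cfg)
    design <- model.matrix(~ sex + growth_group, data = sim$covariates)
    norm <- voom_transform(sim$mirna$counts, tmm_factors(sim$mirna$counts),
                           design)
    grm <- build_grm(sim$genotypes$dosages)
    list(cfg = cfg, sim = sim, design = design, norm = norm, grm = grm)
  })
}

small_fits <- function() {
  cached("small_fits", {
    st <- small_study()
    fit_gblup_all(st$norm, st$grm, st$design)
  })
}

# Brute-force Kendall tau-b by O(n^2) pair counting (tie-corrected).
brute_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0
  tx <- ty <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      sx <- sign(x[j] - x[i])
      sy <- sign(y[j] - y[i])
      if (sx == 0 && sy == 0) next
      if (sx == 0) tx <- tx + 1
      else if (sy == 0) ty <- ty + 1
      else if (sx == sy) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  # pairs tied in x (including both-tied) / in y
  cntx <- table(x); cnty <- table(y)
  n1 <- sum(cntx * (cntx - 1) / 2)
  n2 <- sum(cnty * (cnty - 1) / 2)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# Brute-force Benjamini-Hochberg step-up.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, m / i * p[o[i]])
    q[o[i]] <- prev
  }
  q
}

# GLS per-SNP fixed-effect oracle with V frozen at the no-SNP GBLUP fit.
gls_oracle_t <- function(fit, grm, design) {
  V <- fit$sigma2_a * grm$G + fit$sigma2_e * diag(1 / fit$weights)
  R <- chol(solve(V))
  yw <- as.numeric(R %*% fit$y)
  Xw <- R %*% design
  vapply(seq_len(ncol(grm$Z)), function(j) {
    zw <- as.numeric(R %*% grm$Z[, j])
    XX <- cbind(Xw, zw)
    cf <- qr.coef(qr(XX), yw)
    se <- sqrt(solve(crossprod(XX))[ncol(XX), ncol(XX)])
    unname(cf[length(cf)] / se)
  }, numeric(1))
}

# Dense-matrix restricted log-likelihood, independent of the eigen route.
dense_reml_ll <- function(y, X, G, w, sigma2_a, sigma2_e) {
  n <- length(y)
  p <- ncol(X)
  V <- sigma2_a * G + sigma2_e * diag(1 / w)
  Vi <- solve(V)
  XtViX <- crossprod(X, Vi %*% X)
  beta <- solve(XtViX, crossprod(X, Vi %*% y))
  r <- y - X %*% beta
  as.numeric(-0.5 * ((n - p) * log(2 * pi) +
                       determinant(V, logarithm = TRUE)$modulus +
                       determinant(XtViX, logarithm = TRUE)$modulus +
                       crossprod(r, Vi %*% r)))
}
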