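eq <- function(mirna, chrom, start, end) {
  tibble::tibble(mirna = mirna, chrom = chrom, start = start, end = end)
}
pq <- function(phenotype, chrom, start, end) {
  tibble::tibble(phenotype = phenotype, chrom = chrom, start = start, end = end)
}

test_that("overlap typing follows closed-interval arithmetic", {
  expect_equal(overlap_events(eq("a", 1, 10, 20), pq("p", 1, 5, 25))$overlap_type,
               "eqtl_inside_pqtl")
  expect_equal(nrow(overlap_events(eq("a", 1, 10, 20), pq("p", 1, 21, 30))), 0)
  expect_equal(nrow(overlap_events(eq("a", 1, 10, 20), pq("p", 2, 10, 20))), 0)
  expect_equal(overlap_events(eq("a", 1, 10, 20), pq("p", 1, 10, 20))$overlap_type,
               "identical")
  expect_equal(overlap_events(eq("a", 1, 5, 25), pq("p", 1, 10, 20))$overlap_type,
               "pqtl_inside_eqtl")
  expect_equal(overlap_events(eq("a", 1, 10, 20), pq("p", 1, 5, 15))$overlap_type,
               "partial_upstream")
  expect_equal(overlap_events(eq("a", 1, 10, 20), pq("p", 1, 15, 25))$overlap_type,
               "partial_downstream")
  # closed intervals: single shared base pair is an overlap
  expect_equal(nrow(overlap_events(eq("a", 1, 10, 20), pq("p", 1, 20, 30))), 1)
  # zero-width (single-SNP) peaks are points
  expect_equal(overlap_events(eq("a", 1, 15, 15), pq("p", 1, 10, 20))$overlap_type,
               "eqtl_inside_pqtl")
})

test_that("random interval pairs match the brute-force all-pairs oracle", {
  set.seed(31)
  n <- 1000
  e <- eq(sprintf("m%04d", 1:n), sample(1:4, n, TRUE),
          start = sample(1:900, n, TRUE), end = 0)
  e$end <- e$start + sample(0:100, n, TRUE)
  p <- pq(sprintf("p%04d", 1:n), sample(1:4, n, TRUE),
          start = sample(1:900, n, TRUE), end = 0)
  p$end <- p$start + sample(0:100, n, TRUE)
  # one eQTL against one pQTL per index pair i (keeps the oracle O(n))
  got <- purrr::map_chr(seq_len(n), function(i) {
    ev <- overlap_events(e[i, ], p[i, ])
    if (nrow(ev) == 0) "none" else ev$overlap_type
  })
  oracle <- purrr::map_chr(seq_len(n), function(i) {
    if (e$chrom[i] != p$chrom[i]) return("none")
    if (e$start[i] > p$end[i] || e$end[i] < p$start[i]) return("none")
    if (e$start[i] == p$start[i] && e$end[i] == p$end[i]) return("identical")
    if (e$start[i] >= p$start[i] && e$end[i] <= p$end[i]) return("eqtl_inside_pqtl")
    if (p$start[i] >= e$start[i] && p$end[i] <= e$end[i]) return("pqtl_inside_eqtl")
    if (p$start[i] < e$start[i]) return("partial_upstream") else return("partial_downstream")
  })
  expect_identical(got, oracle)
})

test_that("overlap detection is symmetric with mirrored types", {
  set.seed(8)
  for (r in 1:50) {
    s1 <- sample(1:100, 1); e1 <- s1 + sample(0:30, 1)
    s2 <- sample(1:100, 1); e2 <- s2 + sample(0:30, 1)
    ab <- overlap_events(eq("a", 1, s1, e1), pq("b", 1, s2, e2))
    ba <- overlap_events(eq("b", 1, s2, e2), pq("a", 1, s1, e1))
    expect_equal(nrow(ab), nrow(ba))
    if (nrow(ab) == 1) {
      mirror <- c(identical = "identical",
                  eqtl_inside_pqtl = "pqtl_inside_eqtl",
                  pqtl_inside_eqtl = "eqtl_inside_pqtl",
                  partial_upstream = "partial_downstream",
                  partial_downstream = "partial_upstream")
      expect_equal(ba$overlap_type, unname(mirror[ab$overlap_type]))
    }
  }
})

test_that("corrected expression removes fixed and random effects", {
  fits <- small_fits()
  st <- small_study()
  fit <- fits[[2]]
  r <- correct_expression(fit)
  expect_equal(unname(r), unname(fit$y - as.numeric(st$design %*% fit$beta) -
                                   fit$a_hat))
  # residuals are exactly orthogonal to the design in the weighted metric:
  # r = sigma_e^2 diag(1/w) P y and P X = 0
  expect_lt(max(abs(crossprod(st$design, fit$weights * r))), 1e-8)
  M <- correct_expression_all(fits)
  expect_equal(dim(M), c(12L, 80L))
  expect_equal(M[2, ], r)
})

test_that("Kendall tau-b equals exhaustive pair counting for n <= 8 (with ties)", {
  set.seed(12)
  for (r in 1:60) {
    n <- sample(3:8, 1)
    x <- sample(1:5, n, replace = TRUE) + runif(n) * sample(0:1, 1)
    y <- sample(1:5, n, replace = TRUE) + runif(n) * sample(0:1, 1)
    if (sd(x) == 0 || sd(y) == 0) next
    k <- mireqtl:::kendall_cor(x, y)
    expect_equal(k$tau, brute_tau_b(x, y), tolerance = 1e-12)
    expect_true(k$p >= 0 && k$p <= 1)
  }
  # perfectly discordant ranks
  expect_equal(mireqtl:::kendall_cor(1:6, 6:1)$tau, -1)
  expect_equal(mireqtl:::kendall_cor(1:6, 6:1)$p, 2 / factorial(6))
  # invariance under strictly monotone transforms
  x <- rnorm(20); y <- rnorm(20)
  expect_equal(mireqtl:::kendall_cor(x, y)$tau,
               mireqtl:::kendall_cor(exp(x), y^3 + 5 * y)$tau)
})

test_that("miRNA-target correlation retains negative significant pairs", {
  set.seed(5)
  n <- 80
  samples <- sprintf("S%03d", 1:n)
  m <- matrix(rnorm(2 * n), 2, n, dimnames = list(c("miR-a", "miR-b"), samples))
  g <- matrix(rnorm(3 * n), 3, n, dimnames = list(c("g1", "g2", "g3"), samples))
  g[1, ] <- -1.2 * m[1, ] + rnorm(n, sd = 0.4)  # strong negative
  g[2, ] <- 1.2 * m[1, ] + rnorm(n, sd = 0.4)   # strong positive
  targets <- tibble::tibble(mirna = c("miR-a", "miR-a", "miR-a", "miR-b"),
                            gene = c("g1", "g2", "g3", "g3"))
  tt <- mirna_target_correlation(m, g, targets, fdr = 0.05)
  expect_equal(nrow(tt), 4)
  expect_true(tt$retained[tt$gene == "g1" & tt$mirna == "miR-a"])
  expect_false(tt$retained[tt$gene == "g2" & tt$mirna == "miR-a"])
  expect_true(all(tt$q >= tt$p - 1e-15, na.rm = TRUE))
  # retained set shrinks as fdr decreases
  tt2 <- mirna_target_correlation(m, g, targets, fdr = 1e-6)
  expect_true(all(which(tt2$retained) %in% which(tt$retained)))
  # constant vector: skipped with a warning
  g[3, ] <- 1
  suppressWarnings(expect_warning(
    t3 <- mirna_target_correlation(m, g, targets), "constant"))
  expect_true(is.na(t3$tau[t3$gene == "g3"][1]))
})

test_that("planted negative couplings are recovered from corrected expression", {
  st <- small_study()
  fits <- small_fits()
  sim <- st$sim
  mirna_resid <- correct_expression_all(fits)
  gene_fits <- lapply(rownames(sim$phenogene$genes), function(g) {
    fit_gblup(sim$phenogene$genes[g, ], st$design, st$grm$G, mirna = g)
  })
  names(gene_fits) <- rownames(sim$phenogene$genes)
  gene_resid <- correct_expression_all(gene_fits)
  tt <- mirna_target_correlation(mirna_resid, gene_resid, sim$phenogene$targets)
  strong <- tt[tt$gene == "gene_001", ]
  expect_lt(strong$tau, 0)
  expect_lt(strong$q, 0.05)
})

test_that("Pearson layer matches the closed form and drives the interest rule", {
  x <- c(1.2, 3.4, 2.2, 5.6, 4.4, 7.1, 6.3, 8.8, 9.0, 10.5)
  y <- c(2.0, 2.9, 2.7, 4.9, 5.2, 6.8, 6.1, 8.1, 9.5, 9.9)
  samples <- sprintf("S%02d", 1:10)
  ex <- matrix(x, 1, dimnames = list("g1", samples))
  ph <- matrix(y, 1, dimnames = list("ph1", samples))
  out <- gene_phenotype_correlation(ex, ph)
  r_closed <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(out$r, r_closed, tolerance = 1e-12)
  out_same <- gene_phenotype_correlation(ex, matrix(x, 1, dimnames = list("ph1", samples)))
  expect_equal(out_same$r, 1)
  expect_lt(out_same$p, 1e-12)

  tau_tbl <- tibble::tibble(mirna = "m", gene = c("g1", "g2"), n = 10,
                            tau = c(-0.2, -0.2), p = c(0.001, 0.001),
                            q = c(0.01, 0.01), retained = TRUE)
  gene_pheno <- tibble::tibble(feature = c("g1", "g2"), phenotype = "ph1",
                               n = 10, r = c(-0.3, -0.05), p = c(0.01, 0.8))
  mirna_pheno <- tibble::tibble(feature = "m", phenotype = "ph1", n = 10,
                                r = 0.1, p = 0.5)
  toi <- targets_of_interest(tau_tbl, gene_pheno, mirna_pheno)
  expect_equal(toi$of_interest, c(TRUE, FALSE))
})
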