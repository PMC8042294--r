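test_that("the generator is deterministic given a seed and sensitive to it", {
  cfg <- sim_config(n_samples = 30, n_markers = 60, n_chromosomes = 3,
                    n_mirnas = 5, seed = 9)
  a <- simulate_eqtl_study(cfg)
  b <- simulate_eqtl_study(cfg)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$mirna$counts$counts, b$mirna$counts$counts)
  expect_identical(a$phenogene$phenotypes, b$phenogene$phenotypes)
  cfg2 <- sim_config(n_samples = 30, n_markers = 60, n_chromosomes = 3,
                     n_mirnas = 5, seed = 10)
  c <- simulate_eqtl_study(cfg2)
  expect_false(identical(a$genotypes$dosages, c$genotypes$dosages))
})

test_that("genotypes respect the dosage domain and the MAF filter window", {
  cfg <- sim_config(n_samples = 60, n_markers = 150, n_chromosomes = 3,
                    maf_range = c(0.10, 0.50), n_mirnas = 1, seed = 2)
  g <- simulate_genotypes(cfg)
  expect_true(all(g$dosages %in% 0:2))
  af <- colMeans(g$dosages) / 2
  maf <- pmin(af, 1 - af)
  expect_true(all(maf >= 0.10 - 1e-12))
  expect_true(all(maf <= 0.50 + 1e-12))
  expect_equal(nrow(g$map), 150)
  # contiguous 1-based positions per chromosome
  by_chr <- split(g$map$pos, g$map$chrom)
  expect_true(all(vapply(by_chr, function(p) all(diff(p) > 0), logical(1))))
})

test_that("blockwise LD puts more r2 within blocks than between (brute force)", {
  cfg <- sim_config(n_samples = 1000, n_markers = 100, n_chromosomes = 1,
                    ld_block_size = 50, n_mirnas = 1, seed = 5)
  g <- simulate_genotypes(cfg)
  r2 <- cor(g$dosages)^2
  same_block <- outer(g$map$block, g$map$block, "==")
  diag(same_block) <- NA
  within <- mean(r2[same_block & !is.na(same_block)])
  between <- mean(r2[!same_block & !is.na(same_block)])
  expect_gt(within, between)
  expect_gt(within, 0.2)  # strong LD, F2-like
  expect_lt(between, 0.05)
})

test_that("ld_block_size = 1 gives independent adjacent markers", {
  cfg <- sim_config(n_samples = 1000, n_markers = 80, n_chromosomes = 1,
                    ld_block_size = 1, n_mirnas = 1, seed = 6)
  g <- simulate_genotypes(cfg)
  adj <- vapply(seq_len(79), function(j) {
    cor(g$dosages[, j], g$dosages[, j + 1])
  }, numeric(1))
  expect_lt(abs(mean(adj)), 0.01)
  expect_lt(max(abs(adj)), 4.5 / sqrt(1000))
})

test_that("a large planted causal effect orders latent means by dosage group", {
  cfg <- sim_config(n_samples = 150, n_markers = 40, n_chromosomes = 2,
                    n_mirnas = 2, h2_vector = 0.1,
                    causal_plan = data.frame(mirna = 1, marker = 7,
                                             effect = 3, label = "local"),
                    seed = 8)
  g <- simulate_genotypes(cfg)
  mc <- simulate_mirna_counts(g, cfg)
  lat <- mc$truth$latent[1, ]
  means <- tapply(lat, g$dosages[, 7], mean)
  expect_true(all(diff(means[as.character(0:2)]) > 0))
})

test_that("null architecture has zero polygenic variance and realized h2 tracks the target", {
  cfg0 <- sim_config(n_samples = 50, n_markers = 60, n_chromosomes = 2,
                     n_mirnas = 4, h2_vector = 0, seed = 3)
  g0 <- simulate_genotypes(cfg0)
  mc0 <- simulate_mirna_counts(g0, cfg0)
  expect_equal(max(abs(mc0$truth$polygenic)), 0)

  # law-of-large-numbers: aggregate planted variance ratio near target
  cfg <- sim_config(n_samples = 100, n_markers = 300, n_chromosomes = 3,
                    n_mirnas = 500, h2_vector = 0.4, seed = 4)
  g <- simulate_genotypes(cfg)
  mc <- simulate_mirna_counts(g, cfg)
  v_a <- mean(apply(mc$truth$polygenic, 1, var))
  v_e <- mean(apply(mc$truth$residual, 1, var))
  v_c <- mean(mc$truth$v_count)
  realized <- v_a / (v_a + v_e + v_c)
  expect_lt(abs(realized - 0.4), 0.03)
})

test_that("counts are non-negative integers with library sizes in range", {
  st <- small_study()
  cm <- st$sim$mirna$counts
  expect_true(all(cm$counts >= 0))
  expect_true(all(cm$counts == round(cm$counts)))
  ls <- st$sim$mirna$truth$library_sizes
  expect_true(all(ls >= st$cfg$library_size_range[1] &
                    ls <= st$cfg$library_size_range[2]))
})

test_that("planted couplings and pQTL behave as configured", {
  # coupling -1 with zero noise: perfectly discordant
  cfg <- sim_config(n_samples = 40, n_markers = 30, n_chromosomes = 2,
                    n_mirnas = 2, n_genes = 1,
                    target_plan = data.frame(mirna = 1, gene = 1,
                                             coupling = -1),
                    gene_noise_sd = 0, seed = 12)
  g <- simulate_genotypes(cfg)
  mc <- simulate_mirna_counts(g, cfg)
  pg <- simulate_phenotypes_and_genes(g, mc$truth$latent, cfg)
  expect_equal(cor(mc$truth$latent[1, ], pg$genes[1, ], method = "kendall"), -1)

  # coupling 0 (gene absent from the plan): no systematic association
  taus <- vapply(1:40, function(r) {
    cfg0 <- sim_config(n_samples = 60, n_markers = 30, n_chromosomes = 2,
                       n_mirnas = 1, n_genes = 1, seed = 100 + r)
    g0 <- simulate_genotypes(cfg0)
    mc0 <- simulate_mirna_counts(g0, cfg0)
    pg0 <- simulate_phenotypes_and_genes(g0, mc0$truth$latent, cfg0)
    ct <- cor.test(mc0$truth$latent[1, ], pg0$genes[1, ], method = "kendall",
                   exact = FALSE)
    ct$p.value
  }, numeric(1))
  expect_lte(sum(p.adjust(taus, "BH") < 0.05), 1)

  # pQTL with zero effect: planted marker shows no association
  rej <- vapply(1:30, function(r) {
    cfgp <- sim_config(n_samples = 80, n_markers = 30, n_chromosomes = 2,
                       n_mirnas = 1, n_phenotypes = 1,
                       pqtl_plan = data.frame(phenotype = 1, marker = 5,
                                              effect = 0),
                       seed = 300 + r)
    gp <- simulate_genotypes(cfgp)
    mcp <- simulate_mirna_counts(gp, cfgp)
    pgp <- simulate_phenotypes_and_genes(gp, mcp$truth$latent, cfgp)
    summary(lm(pgp$phenotypes$pheno_01 ~ gp$dosages[, 5]))$coefficients[2, 4] < 0.05
  }, logical(1))
  expect_lte(mean(rej), 0.2)
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(maf_range = c(0.6, 0.7)), class = "mireqtl_config_error")
  expect_error(sim_config(maf_range = c(0.4, 0.2)), class = "mireqtl_config_error")
  expect_error(sim_config(h2_vector = 1), class = "mireqtl_config_error")
  expect_error(sim_config(n_mirnas = 2, h2_vector = c(0.1, 0.2, 0.3)),
               class = "mireqtl_config_error")
  expect_error(
    sim_config(n_markers = 10,
               causal_plan = data.frame(mirna = 1, marker = 11, effect = 1,
                                        label = "local")),
    class = "mireqtl_config_error")
  expect_error(
    sim_config(n_genes = 1,
               target_plan = data.frame(mirna = 1, gene = 1, coupling = 0.5)),
    class = "mireqtl_config_error")
  # heritability unattainable under the count-noise budget is refused
  cfg <- sim_config(n_samples = 30, n_markers = 40, n_chromosomes = 2,
                    n_mirnas = 1, h2_vector = 0.95, seed = 1)
  g <- simulate_genotypes(cfg)
  expect_error(simulate_mirna_counts(g, cfg), class = "mireqtl_config_error")
})

test_that("precursor placement matches the causal plan labels", {
  st <- small_study()
  prec <- st$sim$mirna$precursors
  map <- st$sim$genotypes$map
  causal <- map[30, ]
  p1 <- prec[prec$mirna == "miR-001", ]
  expect_equal(p1$chrom, causal$chrom)
  expect_true(p1$start <= causal$pos && p1$end >= causal$pos)
})
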