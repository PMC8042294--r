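#' Configuration for the synthetic eQTL study generator
#'
#' Builds and validates the configuration driving the simulator. The defaults
#' emulate the design of an F2 resource-population small-RNA study: 174
#' animals, a medium-density SNP panel thinned to 2,000 markers arranged in
#' strong-LD blocks of 50, minor allele frequencies at or above 0.10, sex plus
#' a four-level growth-group as fixed effects, and negative-binomial counts
#' (dispersion 0.1) whose log2 means carry an additive polygenic component.
#'
#' @param n_samples Number of individuals.
#' @param n_markers Number of SNP markers.
#' @param n_chromosomes Number of chromosomes markers are spread over.
#' @param ld_block_size Markers per LD block; 1 gives independent markers.
#' @param ld_rho Latent-haplotype correlation shared within a block, in [0, 1).
#' @param maf_range Length-2 numeric, admissible minor-allele-frequency range,
#'   a sub-interval of (0, 0.5].
#' @param n_mirnas Number of simulated miRNAs.
#' @param h2_vector Per-miRNA narrow-sense heritability of the observed log2
#'   expression, each in [0, 1); the generator inflates the polygenic variance
#'   to offset count-level sampling noise so that realized heritability on the
#'   normalized log-CPM scale matches the target. Recycled to `n_mirnas` if
#'   length 1.
#' @param causal_plan Data frame with columns `mirna`, `marker`, `effect`
#'   (log2-CPM units per allele) and `label` (`"local"` or `"distant"`), one
#'   row per planted causal SNP effect. May be empty.
#' @param library_size_range Length-2 numeric, range of per-sample library
#'   sizes (total mapped small-RNA reads).
#' @param n_phenotypes Number of simulated production phenotypes.
#' @param pqtl_plan Data frame with columns `phenotype`, `marker`, `effect`:
#'   planted phenotype-QTL effects.
#' @param n_genes Number of simulated target-gene expression profiles.
#' @param target_plan Data frame with columns `mirna`, `gene`, `coupling`
#'   (coupling <= 0): planted miRNA-to-target couplings on the latent scale.
#' @param unplaced_mirnas Integer indices of miRNAs whose precursor lies on an
#'   unplaced scaffold (no chromosome assignment).
#' @param dispersion Negative-binomial dispersion of the counts; 0 gives
#'   Poisson sampling.
#' @param latent_sd Standard deviation (log2 units) of the genetic-plus-
#'   environmental latent component of each miRNA.
#' @param baseline_logcpm_range Range the per-miRNA baseline log2-CPM is drawn
#'   from.
#' @param covariate_sd Standard deviation of the simulated sex and growth-group
#'   fixed effects (log2 units).
#' @param gene_noise_sd Residual standard deviation of simulated target genes.
#' @param phenotype_noise_sd Residual standard deviation of phenotypes.
#' @param marker_spacing_bp Base-pair spacing between adjacent markers on a
#'   chromosome.
#' @param seed Integer seed; the same configuration always reproduces the same
#'   data, byte for byte.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
#'
#' @examples
#' cfg <- sim_config(n_samples = 40, n_markers = 100, n_mirnas = 4, seed = 7)
sim_config <- function(n_samples = 174,
                       n_markers = 2000,
                       n_chromosomes = 10,
                       ld_block_size = 50,
                       ld_rho = 0.9,
                       maf_range = c(0.10, 0.50),
                       n_mirnas = 50,
                       h2_vector = 0.15,
                       causal_plan = NULL,
                       library_size_range = c(8e5, 1.2e6),
                       n_phenotypes = 0,
                       pqtl_plan = NULL,
                       n_genes = 0,
                       target_plan = NULL,
                       unplaced_mirnas = integer(),
                       dispersion = 0.1,
                       latent_sd = 1,
                       baseline_logcpm_range = c(4, 10),
                       covariate_sd = 0.5,
                       gene_noise_sd = 1,
                       phenotype_noise_sd = 1,
                       marker_spacing_bp = 3e5,
                       seed = 1L) {
  n_samples <- check_count(n_samples, "n_samples", 2L)
  n_markers <- check_count(n_markers, "n_markers", 1L)
  n_chromosomes <- check_count(n_chromosomes, "n_chromosomes", 1L)
  ld_block_size <- check_count(ld_block_size, "ld_block_size", 1L)
  n_mirnas <- check_count(n_mirnas, "n_mirnas", 1L)
  n_phenotypes <- check_count(n_phenotypes, "n_phenotypes", 0L)
  n_genes <- check_count(n_genes, "n_genes", 0L)
  check_scalar_number(ld_rho, "ld_rho", 0, 1 - 1e-12)
  check_scalar_number(dispersion, "dispersion", 0)
  check_scalar_number(latent_sd, "latent_sd", 0)
  check_scalar_number(covariate_sd, "covariate_sd", 0)
  check_scalar_number(gene_noise_sd, "gene_noise_sd", 0)
  check_scalar_number(phenotype_noise_sd, "phenotype_noise_sd", 0)
  check_scalar_number(marker_spacing_bp, "marker_spacing_bp", 1)
  seed <- check_count(seed, "seed", 0L)

  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2]) {
    stop_bad_config("`maf_range` must be a non-empty sub-interval of (0, 0.5]")
  }
  if (!is.numeric(library_size_range) || length(library_size_range) != 2L ||
      library_size_range[1] <= 0 ||
      library_size_range[1] > library_size_range[2]) {
    stop_bad_config("`library_size_range` must be positive and ordered")
  }
  if (length(h2_vector) == 1L) h2_vector <- rep(h2_vector, n_mirnas)
  if (length(h2_vector) != n_mirnas) {
    stop_bad_config("`h2_vector` must have length 1 or `n_mirnas`")
  }
  if (any(h2_vector < 0 | h2_vector >= 1)) {
    stop_bad_config("all heritabilities in `h2_vector` must lie in [0, 1)")
  }

  causal_plan <- validate_plan(causal_plan, c("mirna", "marker", "effect", "label"))
  pqtl_plan <- validate_plan(pqtl_plan, c("phenotype", "marker", "effect"))
  target_plan <- validate_plan(target_plan, c("mirna", "gene", "coupling"))
  if (nrow(causal_plan) > 0) {
    if (any(causal_plan$marker > n_markers) || any(causal_plan$mirna > n_mirnas)) {
      stop_bad_config("`causal_plan` indexes a marker or miRNA outside the panel")
    }
    if (!all(causal_plan$label %in% c("local", "distant"))) {
      stop_bad_config("`causal_plan$label` must be 'local' or 'distant'")
    }
  }
  if (nrow(pqtl_plan) > 0 &&
      (any(pqtl_plan$marker > n_markers) || any(pqtl_plan$phenotype > n_phenotypes))) {
    stop_bad_config("`pqtl_plan` indexes a marker or phenotype outside the panel")
  }
  if (nrow(target_plan) > 0) {
    if (any(target_plan$gene > n_genes) || any(target_plan$mirna > n_mirnas)) {
      stop_bad_config("`target_plan` indexes a gene or miRNA outside the panel")
    }
    if (any(target_plan$coupling > 0)) {
      stop_bad_config("`target_plan$coupling` must be <= 0 (miRNAs repress targets)")
    }
  }
  unplaced_mirnas <- as.integer(unplaced_mirnas)
  if (any(unplaced_mirnas < 1L | unplaced_mirnas > n_mirnas)) {
    stop_bad_config("`unplaced_mirnas` out of range")
  }

  structure(
    list(
      n_samples = n_samples, n_markers = n_markers,
      n_chromosomes = n_chromosomes, ld_block_size = ld_block_size,
      ld_rho = ld_rho, maf_range = as.numeric(maf_range),
      n_mirnas = n_mirnas, h2_vector = as.numeric(h2_vector),
      causal_plan = causal_plan, library_size_range = as.numeric(library_size_range),
      n_phenotypes = n_phenotypes, pqtl_plan = pqtl_plan,
      n_genes = n_genes, target_plan = target_plan,
      unplaced_mirnas = unplaced_mirnas,
      dispersion = dispersion, latent_sd = latent_sd,
      baseline_logcpm_range = as.numeric(baseline_logcpm_range),
      covariate_sd = covariate_sd, gene_noise_sd = gene_noise_sd,
      phenotype_noise_sd = phenotype_noise_sd,
      marker_spacing_bp = marker_spacing_bp, seed = seed
    ),
    class = "sim_config"
  )
}

validate_plan <- function(plan, cols) {
  if (is.null(plan)) {
    plan <- as_tibble(setNames(rep(list(numeric()), length(cols)), cols))
    if ("label" %in% cols) plan$label <- character()
    return(plan)
  }
  plan <- as_tibble(plan)
  if (!all(cols %in% names(plan))) {
    stop_bad_config(sprintf("plan must have columns: %s", paste(cols, collapse = ", ")))
  }
  plan[cols]
}

#' Simulate blockwise-LD SNP genotypes with a marker map
#'
#' Dosages in \{0, 1, 2\} are built from two latent gametes per individual.
#' Within an LD block every marker shares, per gamete, a latent factor with
#' loading `sqrt(ld_rho)`, so adjacent markers are correlated; blocks are
#' independent. Marker columns whose empirical minor allele frequency falls
#' outside `maf_range` are redrawn (keeping the block factor, so LD survives)
#' until the whole panel passes, mirroring an MAF filter applied to a
#' genotyped population.
#'
#' @param config A [sim_config()] object.
#' @return A list with `dosages` (samples x markers integer matrix, dimnames
#'   set) and `map` (tibble: `marker`, `chrom`, `pos`, `block`, `maf`).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_samples
  m <- config$n_markers
  rho <- config$ld_rho

  per_chrom <- diff(floor(seq(0, m, length.out = config$n_chromosomes + 1L)))
  chrom <- rep(seq_len(config$n_chromosomes), times = per_chrom)
  idx_in_chrom <- unlist(lapply(per_chrom, seq_len), use.names = FALSE)
  pos <- idx_in_chrom * config$marker_spacing_bp
  block_in_chrom <- ceiling(idx_in_chrom / config$ld_block_size)
  block <- paste0("c", chrom, "b", block_in_chrom)

  p <- runif(m, config$maf_range[1], config$maf_range[2])
  blocks <- unique(block)
  block_id <- match(block, blocks)
  # one latent factor per (individual, gamete, block)
  f1 <- matrix(rnorm(n * length(blocks)), n, length(blocks))
  f2 <- matrix(rnorm(n * length(blocks)), n, length(blocks))

  draw_markers <- function(js) {
    d <- matrix(0L, n, length(js))
    for (k in seq_along(js)) {
      j <- js[k]
      thr <- qnorm(p[j])
      z1 <- sqrt(rho) * f1[, block_id[j]] + sqrt(1 - rho) * rnorm(n)
      z2 <- sqrt(rho) * f2[, block_id[j]] + sqrt(1 - rho) * rnorm(n)
      d[, k] <- as.integer(z1 < thr) + as.integer(z2 < thr)
    }
    d
  }

  dosages <- draw_markers(seq_len(m))
  for (iter in seq_len(100L)) {
    af <- colMeans(dosages) / 2
    maf <- pmin(af, 1 - af)
    bad <- which(maf < config$maf_range[1] | maf > config$maf_range[2])
    if (length(bad) == 0L) break
    if (iter > 10L) {
      # stubborn markers: re-draw their target frequency away from the edges
      mid <- config$maf_range[1] + c(0.25, 0.75) * diff(config$maf_range)
      p[bad] <- runif(length(bad), mid[1], mid[2])
    }
    dosages[, bad] <- draw_markers(bad)
  }
  af <- colMeans(dosages) / 2
  maf <- pmin(af, 1 - af)
  if (any(maf < config$maf_range[1] | maf > config$maf_range[2])) {
    abort("could not realize the requested `maf_range`; widen it or add samples",
          class = "mireqtl_config_error")
  }

  marker_ids <- sprintf("M%05d", seq_len(m))
  sample_ids <- sprintf("S%04d", seq_len(n))
  dimnames(dosages) <- list(sample_ids, marker_ids)
  list(
    dosages = dosages,
    map = tibble(marker = marker_ids, chrom = chrom, pos = pos,
                 block = block, maf = maf)
  )
}

#' Simulate balanced categorical covariates
#'
#' Sex (two levels) and a four-level growth group, assigned balanced at
#' random, mirroring the fixed effects of the expression model.
#'
#' @param config A [sim_config()] object.
#' @return Tibble with columns `sample`, `sex`, `growth_group`.
#' @export
simulate_covariates <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 3L)
  n <- config$n_samples
  tibble(
    sample = sprintf("S%04d", seq_len(n)),
    sex = factor(sample(rep(c("F", "M"), length.out = n))),
    growth_group = factor(sample(rep(paste0("G", 1:4), length.out = n)))
  )
}

#' Simulate miRNA counts with planted genetic architecture
#'
#' Each miRNA's latent log2-CPM is
#' `baseline + covariate effects + planted causal-SNP effects + polygenic + e`,
#' where the polygenic term has covariance proportional to the genomic
#' relationship matrix of the simulated dosages, scaled so that its share of
#' the latent (non-causal) variance is the target heritability. Counts are
#' negative binomial (Poisson when `dispersion = 0`) with mean
#' `library_size * 2^latent / 1e6`. Precursor coordinates are placed so that
#' `"local"` planted effects overlap their causal marker and `"distant"` ones
#' land on a different chromosome.
#'
#' @param genotypes Output of [simulate_genotypes()].
#' @param config A [sim_config()] object.
#' @param covariates Optional covariate tibble; defaults to
#'   [simulate_covariates()].
#' @return A list with `counts` (a [count_matrix()]), `covariates`,
#'   `precursors` (tibble: `mirna`, `chrom`, `start`, `end`; `NA` chromosome
#'   for unplaced scaffolds) and `truth` (planted values: `h2`, `causal_plan`,
#'   latent/polygenic matrices, per-miRNA baselines and covariate effects).
#' @export
simulate_mirna_counts <- function(genotypes, config, covariates = NULL) {
  stopifnot(inherits(config, "sim_config"))
  covariates <- covariates %||% simulate_covariates(config)
  set.seed(config$seed + 1L)

  n <- config$n_samples
  k <- config$n_mirnas
  dosages <- genotypes$dosages
  stopifnot(nrow(dosages) == n)

  grm <- build_grm(dosages)
  L <- chol_with_ridge(grm$G)

  X <- model.matrix(~ sex + growth_group, data = covariates)
  mirna_ids <- sprintf("miR-%03d", seq_len(k))
  baseline <- runif(k, config$baseline_logcpm_range[1], config$baseline_logcpm_range[2])
  cov_effects <- matrix(rnorm(k * (ncol(X) - 1L), sd = config$covariate_sd),
                        nrow = k)
  lib_sizes <- round(runif(n, config$library_size_range[1],
                           config$library_size_range[2]))

  latent <- matrix(0, k, n, dimnames = list(mirna_ids, rownames(dosages)))
  polygenic <- matrix(0, k, n, dimnames = dimnames(latent))
  residual <- matrix(0, k, n, dimnames = dimnames(latent))
  # Planted h2 refers to the observed log2 expression: the negative-binomial
  # sampling layer adds (delta-method) variance ~ (log2 e)^2 (phi + 1/mu) on
  # the log2 scale, so the polygenic variance is inflated to keep
  # sigma_a^2 / (latent_sd^2 + v_count) at the target.
  v_count <- (1 / log(2))^2 *
    (config$dispersion + mean(1e6 / lib_sizes) / 2^baseline)
  for (i in seq_len(k)) {
    h2 <- config$h2_vector[i]
    total_var <- config$latent_sd^2 + v_count[i]
    sig2_a <- h2 * total_var
    sig2_env <- config$latent_sd^2 - sig2_a
    if (sig2_env < 0) {
      stop_bad_config(sprintf(
        "h2 = %.2f for miRNA %d is unattainable: count-level noise (%.2f) leaves no room within latent_sd^2 = %.2f",
        h2, i, v_count[i], config$latent_sd^2))
    }
    a <- as.numeric(L %*% rnorm(n)) * sqrt(sig2_a)
    e <- rnorm(n, sd = sqrt(sig2_env))
    mu <- baseline[i] + as.numeric(X[, -1, drop = FALSE] %*% cov_effects[i, ])
    plan_i <- config$causal_plan[config$causal_plan$mirna == i, , drop = FALSE]
    if (nrow(plan_i) > 0) {
      mu <- mu + as.numeric(dosages[, plan_i$marker, drop = FALSE] %*% plan_i$effect)
    }
    polygenic[i, ] <- a
    residual[i, ] <- e
    latent[i, ] <- mu + a + e
  }

  mu_counts <- sweep(2^latent, 2, lib_sizes / 1e6, `*`)
  counts <- matrix(0L, k, n, dimnames = dimnames(latent))
  if (config$dispersion > 0) {
    counts[] <- as.integer(rnbinom(length(mu_counts), size = 1 / config$dispersion,
                                   mu = as.numeric(mu_counts)))
  } else {
    counts[] <- as.integer(rpois(length(mu_counts), as.numeric(mu_counts)))
  }

  precursors <- place_precursors(genotypes$map, config, mirna_ids)

  truth <- list(
    h2 = setNames(config$h2_vector, mirna_ids),
    causal_plan = dplyr::mutate(config$causal_plan,
                                mirna_id = mirna_ids[.data$mirna],
                                marker_id = genotypes$map$marker[.data$marker]),
    baseline = setNames(baseline, mirna_ids),
    cov_effects = cov_effects,
    latent = latent, polygenic = polygenic, residual = residual,
    v_count = setNames(v_count, mirna_ids),
    library_sizes = setNames(lib_sizes, rownames(dosages))
  )
  list(
    counts = count_matrix(counts, library_sizes = lib_sizes),
    covariates = covariates,
    precursors = precursors,
    truth = truth
  )
}

chol_with_ridge <- function(G, ridge = 1e-8) {
  t(chol(G + diag(ridge * mean(diag(G)), nrow(G))))
}

place_precursors <- function(map, config, mirna_ids) {
  k <- config$n_mirnas
  chrom <- integer(k)
  start <- numeric(k)
  half_width <- 5e3
  chroms <- sort(unique(map$chrom))
  # deterministic default placement, cycling over chromosomes
  for (i in seq_len(k)) {
    chrom[i] <- chroms[((i - 1L) %% length(chroms)) + 1L]
    on_chrom <- map[map$chrom == chrom[i], ]
    start[i] <- on_chrom$pos[((i * 7L) %% nrow(on_chrom)) + 1L] + 1e4
  }
  plan <- config$causal_plan
  for (r in seq_len(nrow(plan))) {
    i <- plan$mirna[r]
    mk <- map[plan$marker[r], ]
    if (plan$label[r] == "local") {
      chrom[i] <- mk$chrom
      start[i] <- mk$pos - half_width
    } else if (chrom[i] == mk$chrom) {
      chrom[i] <- chroms[(match(mk$chrom, chroms) %% length(chroms)) + 1L]
    }
  }
  chrom[config$unplaced_mirnas] <- NA_integer_
  tibble(
    mirna = mirna_ids,
    chrom = chrom,
    start = pmax(1, round(start)),
    end = pmax(1, round(start)) + 2L * half_width
  )
}

#' Simulate phenotypes, target-gene expression and target lists
#'
#' Phenotypes are planted pQTL marker effects plus a sex effect and Gaussian
#' noise. Target genes follow
#' `baseline + coupling * (miRNA latent) + noise` with coupling <= 0, the
#' assumed repressive relationship between a miRNA and its targets; genes not
#' named in the plan are pure noise. Gene coordinates are placed
#' deterministically on the simulated map.
#'
#' @param genotypes Output of [simulate_genotypes()].
#' @param mirna_latents miRNAs x samples latent log2-expression matrix (the
#'   `truth$latent` element of [simulate_mirna_counts()]).
#' @param config A [sim_config()] object.
#' @param covariates Optional covariate tibble; defaults to
#'   [simulate_covariates()].
#' @return List with `phenotypes` (tibble, one column per phenotype),
#'   `genes` (genes x samples matrix), `gene_map` (tibble: `gene`, `chrom`,
#'   `start`, `end`), `targets` (tibble: `mirna`, `gene`) and `truth`.
#' @export
simulate_phenotypes_and_genes <- function(genotypes, mirna_latents, config,
                                          covariates = NULL) {
  stopifnot(inherits(config, "sim_config"))
  covariates <- covariates %||% simulate_covariates(config)
  set.seed(config$seed + 2L)
  n <- config$n_samples
  dosages <- genotypes$dosages
  sample_ids <- rownames(dosages)

  phen <- matrix(0, n, config$n_phenotypes)
  if (config$n_phenotypes > 0) {
    sex_num <- as.numeric(covariates$sex == levels(covariates$sex)[2])
    sex_eff <- rnorm(config$n_phenotypes, sd = config$covariate_sd)
    for (q in seq_len(config$n_phenotypes)) {
      plan_q <- config$pqtl_plan[config$pqtl_plan$phenotype == q, , drop = FALSE]
      g <- if (nrow(plan_q) > 0) {
        as.numeric(dosages[, plan_q$marker, drop = FALSE] %*% plan_q$effect)
      } else 0
      phen[, q] <- g + sex_eff[q] * sex_num +
        rnorm(n, sd = config$phenotype_noise_sd)
    }
  }
  colnames(phen) <- if (config$n_phenotypes > 0) {
    sprintf("pheno_%02d", seq_len(config$n_phenotypes))
  } else character()
  phenotypes <- dplyr::bind_cols(tibble(sample = sample_ids), as_tibble(phen))

  gene_ids <- sprintf("gene_%03d", seq_len(config$n_genes))
  genes <- matrix(rnorm(config$n_genes * n, sd = config$gene_noise_sd),
                  config$n_genes, n, dimnames = list(gene_ids, sample_ids))
  if (config$n_genes > 0) {
    genes <- genes + rnorm(config$n_genes, mean = 5, sd = 1) # baselines
    plan <- config$target_plan
    for (r in seq_len(nrow(plan))) {
      g <- plan$gene[r]
      genes[g, ] <- genes[g, ] +
        plan$coupling[r] * mirna_latents[plan$mirna[r], sample_ids]
    }
  }

  map <- genotypes$map
  chroms <- sort(unique(map$chrom))
  gene_map <- tibble(
    gene = gene_ids,
    chrom = chroms[((seq_len(config$n_genes) - 1L) %% length(chroms)) + 1L],
    start = 1e4 + (seq_len(config$n_genes) * 911L) %% max(map$pos)
  )
  gene_map$end <- gene_map$start + 2e4

  targets <- tibble(
    mirna = sprintf("miR-%03d", as.integer(config$target_plan$mirna)),
    gene = gene_ids[config$target_plan$gene]
  )
  truth <- list(pqtl_plan = config$pqtl_plan, target_plan = config$target_plan)
  list(phenotypes = phenotypes, genes = genes, gene_map = gene_map,
       targets = targets, truth = truth)
}

#' Simulate a complete miRNA-eQTL study
#'
#' Convenience wrapper running [simulate_genotypes()],
#' [simulate_covariates()], [simulate_mirna_counts()] and
#' [simulate_phenotypes_and_genes()] from one configuration.
#'
#' @param config A [sim_config()] object.
#' @return A list with elements `genotypes`, `covariates`, `mirna`
#'   (counts/precursors/truth) and `phenogene` (phenotypes, genes, targets),
#'   plus the `config` itself.
#' @export
simulate_eqtl_study <- function(config) {
  genotypes <- simulate_genotypes(config)
  covariates <- simulate_covariates(config)
  mirna <- simulate_mirna_counts(genotypes, config, covariates)
  phenogene <- simulate_phenotypes_and_genes(genotypes, mirna$truth$latent,
                                             config, covariates)
  list(config = config, genotypes = genotypes, covariates = covariates,
       mirna = mirna, phenogene = phenogene)
}
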