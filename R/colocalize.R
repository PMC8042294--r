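#' Type the genomic overlaps between eQTL peaks and pQTL peaks
#'
#' For every same-chromosome (eQTL peak, pQTL peak) pair whose closed
#' intervals intersect, emits one event typed as `identical`,
#' `eqtl_inside_pqtl`, `pqtl_inside_eqtl`, `partial_upstream` (the pQTL
#' overhangs the eQTL's lower-coordinate side) or `partial_downstream`.
#' Single-SNP peaks have zero width and are treated as points; any nonzero
#' closed-interval intersection counts as overlap.
#'
#' @param eqtl_peaks Tibble with `mirna`, `chrom`, `start`, `end` (e.g. from
#'   [call_peaks()]).
#' @param pqtl_peaks Tibble with `phenotype`, `chrom`, `start`, `end`, and
#'   optionally `peak_snp`, `peak_pos`.
#' @return Tibble, one row per event: ids, chromosome, both ranges,
#'   `overlap_type`.
#' @export
overlap_events <- function(eqtl_peaks, pqtl_peaks) {
  pq <- dplyr::rename(pqtl_peaks, pqtl_start = "start", pqtl_end = "end")
  ev <- dplyr::inner_join(
    dplyr::select(eqtl_peaks, "mirna", "chrom", "start", "end"),
    pq, by = "chrom", relationship = "many-to-many")
  ev <- dplyr::filter(ev, .data$start <= .data$pqtl_end,
                      .data$end >= .data$pqtl_start)
  dplyr::mutate(ev, overlap_type = dplyr::case_when(
    start == pqtl_start & end == pqtl_end ~ "identical",
    start >= pqtl_start & end <= pqtl_end ~ "eqtl_inside_pqtl",
    pqtl_start >= start & pqtl_end <= end ~ "pqtl_inside_eqtl",
    pqtl_start < start ~ "partial_upstream",
    TRUE ~ "partial_downstream"
  ))
}

#' Model-corrected expression values
#'
#' Removes both the fitted fixed effects and the predicted random (polygenic)
#' effect from a response: `residual = y - X beta_hat - a_hat`. These
#' corrected values are the inputs to the correlation layers. Fixed-only
#' correction is available with `include_random = FALSE`.
#'
#' @param fit A [fit_gblup()] object.
#' @param include_random Subtract the predicted breeding values too (default).
#' @return Named numeric vector of corrected values, one per sample.
#' @export
correct_expression <- function(fit, include_random = TRUE) {
  stopifnot(inherits(fit, "gblup_fit"))
  r <- fit$y - as.numeric(fit$X %*% fit$beta)
  if (include_random) r <- r - fit$a_hat
  setNames(r, names(fit$a_hat))
}

#' @rdname correct_expression
#' @param fits Named list of `gblup_fit` objects.
#' @return For `correct_expression_all()`, a features x samples matrix.
#' @export
correct_expression_all <- function(fits, include_random = TRUE) {
  t(vapply(fits, correct_expression, numeric(fits[[1]]$n),
           include_random = include_random))
}

#' Residualize phenotypes on their covariate model
#'
#' Ordinary least-squares residuals of each phenotype column on a covariate
#' formula (defaults to sex + growth group; covariate models may vary by
#' phenotype, so a named list of formulas is accepted).
#'
#' @param phenotypes Tibble with a `sample` column and one numeric column per
#'   phenotype.
#' @param covariates Covariate tibble with a matching `sample` column.
#' @param formulas Single RHS formula applied to every phenotype, or a named
#'   list (by phenotype) of formulas.
#' @return Phenotypes x samples matrix of corrected values.
#' @export
correct_phenotypes <- function(phenotypes, covariates,
                               formulas = ~ sex + growth_group) {
  stopifnot("sample" %in% names(phenotypes), "sample" %in% names(covariates))
  cov <- covariates[match(phenotypes$sample, covariates$sample), , drop = FALSE]
  pheno_cols <- setdiff(names(phenotypes), "sample")
  out <- matrix(NA_real_, length(pheno_cols), nrow(phenotypes),
                dimnames = list(pheno_cols, phenotypes$sample))
  for (ph in pheno_cols) {
    f <- if (is.list(formulas)) formulas[[ph]] %||% ~ sex + growth_group else formulas
    X <- model.matrix(f, data = cov)
    y <- phenotypes[[ph]]
    out[ph, ] <- y - X %*% qr.coef(qr(X), y)
  }
  out
}

# Kendall tau-b with a two-sided p-value: exact permutation enumeration for
# n <= 8, otherwise the tie-corrected normal approximation (cor.test).
kendall_cor <- function(x, y) {
  n <- length(x)
  tau <- suppressWarnings(cor(x, y, method = "kendall"))
  if (!is.finite(tau)) return(list(tau = NA_real_, p = NA_real_))
  if (n <= 8) {
    perms <- all_permutations(n)
    taus <- apply(perms, 1, function(idx) {
      suppressWarnings(cor(x, y[idx], method = "kendall"))
    })
    p <- mean(abs(taus) >= abs(tau) - 1e-12)
  } else {
    p <- suppressWarnings(
      cor.test(x, y, method = "kendall", exact = FALSE)$p.value)
  }
  list(tau = tau, p = p)
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Kendall correlation of miRNAs with their predicted target genes
#'
#' For each (miRNA, target gene) pair, computes Kendall's tau-b between
#' model-corrected expression values on the samples present in both sets,
#' with a two-sided p-value and Benjamini-Hochberg q-values across all pairs
#' jointly. Pairs with `tau < 0` and `q < fdr` are flagged `retained` — the
#' assumed repressive relationship between a miRNA and its targets. Pairs
#' with a constant vector are skipped with a warning.
#'
#' @param mirna_resid miRNAs x samples matrix of corrected miRNA expression
#'   (named columns).
#' @param gene_resid Genes x samples matrix of corrected gene expression.
#' @param targets Tibble with columns `mirna`, `gene`, one row per pair.
#' @param fdr Retention threshold on q.
#' @return Tibble: `mirna`, `gene`, `n`, `tau`, `p`, `q`, `retained`.
#' @export
mirna_target_correlation <- function(mirna_resid, gene_resid, targets,
                                     fdr = 0.05) {
  mirna_resid <- as.matrix(mirna_resid)
  gene_resid <- as.matrix(gene_resid)
  shared <- intersect(colnames(mirna_resid), colnames(gene_resid))
  if (length(shared) < 3) {
    abort("fewer than 3 shared samples between miRNA and gene sets",
          class = "mireqtl_input_error")
  }
  res <- purrr::pmap_dfr(targets[c("mirna", "gene")], function(mirna, gene) {
    x <- mirna_resid[mirna, shared]
    y <- gene_resid[gene, shared]
    if (sd(x) == 0 || sd(y) == 0) {
      warn(sprintf("constant vector for pair (%s, %s); skipped", mirna, gene))
      return(tibble(mirna = mirna, gene = gene, n = length(shared),
                    tau = NA_real_, p = NA_real_))
    }
    k <- kendall_cor(x, y)
    tibble(mirna = mirna, gene = gene, n = length(shared),
           tau = k$tau, p = k$p)
  })
  res$q <- NA_real_
  ok <- !is.na(res$p)
  res$q[ok] <- p.adjust(res$p[ok], method = "BH")
  res$retained <- !is.na(res$tau) & res$tau < 0 & res$q < fdr
  res
}

#' Pearson correlation of corrected expression with corrected phenotypes
#'
#' Two-sided Pearson correlation (t reference on n - 2 df) between each
#' requested (expression profile, phenotype) pair of model-corrected values.
#'
#' @param expr_resid Features x samples matrix of corrected expression (miRNAs
#'   or genes).
#' @param pheno_resid Phenotypes x samples matrix of corrected phenotypes.
#' @param pairs Tibble with columns `feature`, `phenotype`; defaults to all
#'   combinations.
#' @return Tibble: `feature`, `phenotype`, `n`, `r`, `p`.
#' @export
gene_phenotype_correlation <- function(expr_resid, pheno_resid, pairs = NULL) {
  expr_resid <- as.matrix(expr_resid)
  pheno_resid <- as.matrix(pheno_resid)
  shared <- intersect(colnames(expr_resid), colnames(pheno_resid))
  if (length(shared) < 3) {
    abort("fewer than 3 shared samples between expression and phenotype sets",
          class = "mireqtl_input_error")
  }
  pairs <- pairs %||% tidyr::expand_grid(feature = rownames(expr_resid),
                                         phenotype = rownames(pheno_resid))
  purrr::pmap_dfr(pairs[c("feature", "phenotype")], function(feature, phenotype) {
    x <- expr_resid[feature, shared]
    y <- pheno_resid[phenotype, shared]
    if (sd(x) == 0 || sd(y) == 0) {
      warn(sprintf("constant vector for pair (%s, %s); skipped",
                   feature, phenotype))
      return(tibble(feature = feature, phenotype = phenotype,
                    n = length(shared), r = NA_real_, p = NA_real_))
    }
    ct <- cor.test(x, y, method = "pearson")
    tibble(feature = feature, phenotype = phenotype, n = length(shared),
           r = unname(ct$estimate), p = ct$p.value)
  })
}

#' Report target genes of interest
#'
#' A target gene is "of interest" for a (miRNA, gene, phenotype) triad when it
#' is negatively correlated with the miRNA at `q < fdr` (the retained set of
#' [mirna_target_correlation()]) and either the gene-phenotype or the
#' miRNA-phenotype Pearson correlation reaches `p < p_threshold`.
#'
#' @param tau_tbl Output of [mirna_target_correlation()].
#' @param gene_pheno Output of [gene_phenotype_correlation()] on genes
#'   (feature = gene).
#' @param mirna_pheno Output of [gene_phenotype_correlation()] on miRNAs
#'   (feature = miRNA).
#' @param fdr Retention threshold on the miRNA-target q-value.
#' @param p_threshold Nominal threshold on the phenotype correlations.
#' @return Tibble, one row per (gene, phenotype): the three correlation layers
#'   with their p-values and an `of_interest` flag.
#' @export
targets_of_interest <- function(tau_tbl, gene_pheno, mirna_pheno,
                                fdr = 0.05, p_threshold = 0.05) {
  retained <- dplyr::filter(tau_tbl, !is.na(.data$tau),
                            .data$tau < 0, .data$q < fdr)
  out <- retained |>
    dplyr::inner_join(
      dplyr::rename(gene_pheno, gene = "feature",
                    r_gene_pheno = "r", p_gene_pheno = "p"),
      by = "gene", relationship = "many-to-many") |>
    dplyr::inner_join(
      dplyr::rename(mirna_pheno, mirna = "feature",
                    r_mirna_pheno = "r", p_mirna_pheno = "p"),
      by = c("mirna", "phenotype")
    )
  dplyr::mutate(
    out,
    of_interest = (!is.na(.data$p_gene_pheno) & .data$p_gene_pheno < p_threshold) |
      (!is.na(.data$p_mirna_pheno) & .data$p_mirna_pheno < p_threshold)
  ) |>
    dplyr::select("mirna", "gene", "phenotype", "tau", "q",
                  "r_gene_pheno", "p_gene_pheno",
                  "r_mirna_pheno", "p_mirna_pheno", "of_interest")
}
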