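#' Conditional GWA: refit with a peak SNP as a fixed effect
#'
#' Repeats the GBLUP association analysis for one miRNA with the genotype of a
#' chosen SNP (normally the peak SNP, selected by minimum p) added to the
#' fixed effects, then re-backsolves and re-calls peaks on the conditional
#' fit with the fixed SNP excluded from the test set. The variance explained
#' by the SNP is `var_q = b^2 * var(z_peak)` (sample variance, n-1
#' denominator) and its share of phenotypic variance is
#' `prop_var = var_q / (sigma_a^2 + sigma_e^2 + var_q)`, by default with the
#' conditional fit's variance components.
#'
#' Outcomes mirror the three interpretive cases of a conditional eQTL scan:
#' `explained_by_snp` when no SNP anywhere stays significant,
#' `cross_genome_correlation` when the only peaks lost lie on a different
#' chromosome than the fixed SNP while other signal remains (the fixed SNP
#' tags a correlated locus elsewhere in the genome), and `independent_loci`
#' when significant peaks remain. Collinearity of the SNP with the existing
#' design (e.g. a monomorphic SNP, or perfect LD with an already-fixed
#' column) is recorded as `collinear_failure`, not raised.
#'
#' @param fit The unconditional [fit_gblup()] for the miRNA (carries `y`, the
#'   design, `G` and the precision weights).
#' @param snp_dosages Raw dosage vector (0/1/2) of the SNP to fix, in sample
#'   order.
#' @param snp_id Marker id of the fixed SNP.
#' @param grm A [build_grm()] object (for the re-backsolve).
#' @param map Marker map tibble (`marker`, `chrom`, `pos`).
#' @param fdr FDR threshold for the conditional peak calling.
#' @param merge_gap_bp Passed to [call_peaks()].
#' @param original_peaks Optional: this miRNA's peaks from the unconditional
#'   scan; needed to distinguish `cross_genome_correlation` from
#'   `independent_loci`.
#' @param encoding `"dosage"` fixes the SNP as one additive covariate (1 df,
#'   scalar effect `b`); `"factor"` fixes it as a genotype factor (`b` is then
#'   undefined and `var_q` is the sample variance of the genotype-class fitted
#'   values).
#' @param components Variance components used in the `prop_var` denominator:
#'   the `"conditional"` (default) or the `"unconditional"` fit's.
#' @param method Multiple-testing adjustment for the conditional scan.
#' @return An object of class `"gblup_conditional"`: `mirna`, `fixed_snp`,
#'   `b`, `var_q`, `prop_var`, `outcome`, `peaks_remaining` (tibble),
#'   `associations` (conditional scan tibble), `refit` (the conditional
#'   `gblup_fit`, `NULL` on collinear failure).
#' @export
conditional_fit <- function(fit, snp_dosages, snp_id, grm, map,
                            fdr = 0.05, merge_gap_bp = 20e6,
                            original_peaks = NULL,
                            encoding = c("dosage", "factor"),
                            components = c("conditional", "unconditional"),
                            method = c("BH", "storey")) {
  stopifnot(inherits(fit, "gblup_fit"))
  encoding <- match.arg(encoding)
  components <- match.arg(components)
  method <- match.arg(method)
  z <- as.numeric(snp_dosages)
  stopifnot(length(z) == fit$n)

  fail <- function() {
    structure(
      list(mirna = fit$mirna, fixed_snp = snp_id, b = NA_real_,
           var_q = NA_real_, prop_var = NA_real_,
           outcome = "collinear_failure",
           peaks_remaining = empty_peaks(),
           associations = NULL, refit = NULL),
      class = "gblup_conditional")
  }

  var_z <- var(z)
  if (!is.finite(var_z) || var_z == 0) return(fail())
  X2 <- if (encoding == "dosage") {
    cbind(fit$X, fixed_snp = z)
  } else {
    cbind(fit$X, model.matrix(~ factor(z))[, -1, drop = FALSE])
  }
  if (qr(X2)$rank < ncol(X2)) return(fail())

  refit <- fit_gblup(fit$y, X2, fit$G, weights = fit$weights, mirna = fit$mirna)

  if (encoding == "dosage") {
    b <- unname(refit$beta["fixed_snp"])
    var_q <- b^2 * var_z
  } else {
    geno_cols <- setdiff(colnames(X2), colnames(fit$X))
    fitted_geno <- X2[, geno_cols, drop = FALSE] %*% refit$beta[geno_cols]
    b <- NA_real_
    var_q <- var(as.numeric(fitted_geno))
  }
  comp <- if (components == "conditional") refit else fit
  prop_var <- var_q / (comp$sigma2_a + comp$sigma2_e + var_q)

  assoc <- suppressWarnings(
    gwa_scan(refit, grm, map, method = method)
  )
  assoc <- dplyr::filter(assoc, .data$marker_id != snp_id)
  assoc$q <- adjust_pvalues(assoc$p, ifelse(method == "BH", "BH", "storey"))
  peaks <- call_peaks(assoc, fdr = fdr, merge_gap_bp = merge_gap_bp)

  outcome <- if (nrow(peaks) == 0) {
    "explained_by_snp"
  } else if (!is.null(original_peaks) && nrow(original_peaks) > 0) {
    snp_chrom <- map$chrom[match(snp_id, map$marker)]
    lost <- dplyr::anti_join(
      dplyr::select(original_peaks, "mirna", "chrom"),
      dplyr::select(peaks, "mirna", "chrom"),
      by = c("mirna", "chrom"))
    if (nrow(lost) > 0 && all(lost$chrom != snp_chrom)) {
      "cross_genome_correlation"
    } else {
      "independent_loci"
    }
  } else {
    "independent_loci"
  }

  structure(
    list(mirna = fit$mirna, fixed_snp = snp_id, b = b, var_q = var_q,
         prop_var = prop_var, outcome = outcome,
         peaks_remaining = peaks, associations = assoc, refit = refit),
    class = "gblup_conditional")
}

#' Conditional replication GWA on a phenotype-QTL peak SNP
#'
#' Identical contract to [conditional_fit()], used when testing whether a
#' colocalized pQTL's peak SNP accounts for a miRNA's eQTL signal: the pQTL
#' peak SNP genotypes are added as a fixed effect in a replication GWA. The
#' result is tagged with the phenotype context so it can be reported alongside
#' the colocalization event it tests.
#'
#' @inheritParams conditional_fit
#' @param phenotype Name of the phenotype whose pQTL supplies the fixed SNP.
#' @param ... Passed to [conditional_fit()].
#' @return A `gblup_conditional` with a `phenotype` element.
#' @export
condition_on_pqtl_snp <- function(fit, snp_dosages, snp_id, grm, map,
                                  phenotype = NA_character_, ...) {
  res <- conditional_fit(fit, snp_dosages, snp_id, grm, map, ...)
  res$phenotype <- phenotype
  res
}

#' @export
print.gblup_conditional <- function(x, ...) {
  cat(sprintf(
    "<gblup_conditional %s | %s> outcome: %s; b = %.4g, prop_var = %.3f; %d peak(s) remain\n",
    x$mirna, x$fixed_snp, x$outcome,
    ifelse(is.na(x$b), NA, x$b), ifelse(is.na(x$prop_var), NA, x$prop_var),
    nrow(x$peaks_remaining)))
  invisible(x)
}

#' @rdname conditional_fit
#' @param x A `gblup_conditional`.
#' @param ... Unused.
#' @method tidy gblup_conditional
#' @export
tidy.gblup_conditional <- function(x, ...) {
  tibble(
    mirna = x$mirna, fixed_snp = x$fixed_snp,
    phenotype = x$phenotype %||% NA_character_,
    b = x$b, var_q = x$var_q, prop_var = x$prop_var, outcome = x$outcome,
    n_peaks_remaining = nrow(x$peaks_remaining),
    snps_remaining = sum(x$peaks_remaining$n_snps),
    remaining_peak_snps = paste(x$peaks_remaining$peak_snp, collapse = ","),
    remaining_peak_chroms = paste(x$peaks_remaining$chrom, collapse = ",")
  )
}
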