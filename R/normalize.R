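#' Raw small-RNA count matrix
#'
#' Container for non-negative integer counts, miRNAs in rows, samples
#' (libraries) in columns. Library sizes default to column sums but can be
#' supplied when the totals include reads not in the matrix.
#'
#' @param counts Numeric matrix of non-negative integers with rownames
#'   (miRNA ids) and colnames (sample ids).
#' @param library_sizes Optional positive numeric vector, one per sample.
#' @return An object of class `"count_matrix"`.
#' @export
count_matrix <- function(counts, library_sizes = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("`counts` must be non-negative integers", class = "mireqtl_input_error")
  }
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("feature_%d", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- sprintf("sample_%d", seq_len(ncol(counts)))
  }
  library_sizes <- library_sizes %||% colSums(counts)
  library_sizes <- as.numeric(library_sizes)
  if (length(library_sizes) != ncol(counts) || any(library_sizes <= 0)) {
    abort("`library_sizes` must be positive, one per sample",
          class = "mireqtl_input_error")
  }
  structure(
    list(counts = counts,
         mirna_ids = rownames(counts),
         sample_ids = colnames(counts),
         library_sizes = setNames(library_sizes, colnames(counts))),
    class = "count_matrix"
  )
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d miRNAs x %d libraries (median library size %s)\n",
              nrow(x$counts), ncol(x$counts),
              format(stats::median(x$library_sizes), big.mark = ",")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Counts per million on raw library sizes
#'
#' CPM without normalization factors, as used by the expression filter (which
#' runs before TMM factors exist).
#'
#' @param counts A [count_matrix()].
#' @return Numeric matrix of CPM values, same shape as the counts.
#' @export
raw_cpm <- function(counts) {
  sweep(counts$counts, 2, counts$library_sizes / 1e6, `/`)
}

#' Remove miRNAs expressed below a CPM threshold in too many libraries
#'
#' A miRNA is dropped iff its CPM (computed on raw library sizes, before any
#' TMM scaling) falls below `cpm_threshold` in at least `min_fail_libraries`
#' libraries. With the defaults this is the "< 1 CPM in >= 44 libraries" rule
#' used with 174-library small-RNA panels. Retained miRNAs keep their order.
#'
#' @param counts A [count_matrix()].
#' @param cpm_threshold CPM below which a library counts as failing.
#' @param min_fail_libraries Minimum number of failing libraries for removal.
#' @return A filtered [count_matrix()] (library sizes unchanged).
#' @export
filter_low_expression <- function(counts, cpm_threshold = 1,
                                  min_fail_libraries = 44) {
  stopifnot(inherits(counts, "count_matrix"))
  check_scalar_number(cpm_threshold, "cpm_threshold", 0)
  min_fail_libraries <- check_count(min_fail_libraries, "min_fail_libraries", 0L)
  if (min_fail_libraries > ncol(counts$counts)) {
    stop_bad_config("`min_fail_libraries` exceeds the number of libraries")
  }
  n_fail <- rowSums(raw_cpm(counts) < cpm_threshold)
  keep <- n_fail < min_fail_libraries
  if (!any(keep)) {
    warn("expression filter removed every miRNA")
  }
  count_matrix(counts$counts[keep, , drop = FALSE],
               library_sizes = counts$library_sizes)
}

#' Trimmed-mean-of-M (TMM) normalization factors
#'
#' Per-sample scaling factors from a doubly trimmed weighted mean of
#' log-expression ratios (M) against a reference sample, the library whose
#' upper-quartile CPM is closest to the mean upper-quartile. M and A sets are
#' trimmed by `logratio_trim` and `abs_trim` and averaged with
#' inverse-asymptotic-variance weights; factors are rescaled so their log-mean
#' is zero. Computation is delegated to `edgeR::calcNormFactors`.
#'
#' @param counts A [count_matrix()] (normally already expression-filtered).
#' @param logratio_trim Fraction of M values trimmed from each tail.
#' @param abs_trim Fraction of A values trimmed from each tail.
#' @return Named numeric vector of factors, one per sample, geometric mean 1.
#' @export
tmm_factors <- function(counts, logratio_trim = 0.30, abs_trim = 0.05) {
  stopifnot(inherits(counts, "count_matrix"))
  if (ncol(counts$counts) < 2L) {
    abort("TMM needs at least two samples", class = "mireqtl_input_error")
  }
  f <- edgeR::calcNormFactors(counts$counts, lib.size = counts$library_sizes,
                              method = "TMM", logratioTrim = logratio_trim,
                              sumTrim = abs_trim)
  setNames(as.numeric(f), counts$sample_ids)
}

#' Voom transform: log-CPM with per-observation precision weights
#'
#' Computes `log2((count + 0.5) / (library_size * factor + 1) * 1e6)` and, via
#' the limma voom procedure, an empirical mean-variance trend (lowess of the
#' square-root residual standard deviation against mean log2 count from a
#' per-miRNA linear fit on `design`) whose inverse fourth power at each
#' observation's fitted log-count gives the precision weight. Weights are
#' floored at `weight_floor`. With fewer than 10 miRNAs the trend cannot be
#' estimated and all weights are set to 1 with a warning.
#'
#' @param counts A filtered [count_matrix()].
#' @param factors TMM factors from [tmm_factors()], aligned to the samples;
#'   defaults to all 1.
#' @param design Fixed-effect design matrix used for the mean-variance fit
#'   (defaults to an intercept; pass the expression model's design, e.g.
#'   `model.matrix(~ sex + growth_group, covariates)`, to match downstream
#'   fits).
#' @param span Lowess span of the mean-variance trend.
#' @param weight_floor Lower bound applied to the precision weights.
#' @return An object of class `"voom_norm"`: list with `logcpm` and `weights`
#'   matrices (miRNAs x samples), `norm_factors`, `library_sizes` and the
#'   `design` used.
#' @export
voom_transform <- function(counts, factors = NULL, design = NULL, span = 0.5,
                           weight_floor = 1e-6) {
  stopifnot(inherits(counts, "count_matrix"))
  n <- ncol(counts$counts)
  factors <- factors %||% setNames(rep(1, n), counts$sample_ids)
  if (length(factors) != n || any(factors <= 0)) {
    abort("`factors` must be positive, one per sample",
          class = "mireqtl_input_error")
  }
  design <- design %||% matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  eff_lib <- counts$library_sizes * factors
  logcpm <- log2(sweep(counts$counts + 0.5, 2, eff_lib + 1, `/`) * 1e6)

  if (nrow(counts$counts) < 10L) {
    warn("fewer than 10 miRNAs: mean-variance trend not fit, weights set to 1")
    weights <- matrix(1, nrow(logcpm), ncol(logcpm), dimnames = dimnames(logcpm))
  } else {
    v <- limma::voom(counts$counts, design = design,
                     lib.size = eff_lib, span = span)
    weights <- pmax(v$weights, weight_floor)
    dimnames(weights) <- dimnames(logcpm)
    # limma's E equals the closed form above; keep our matrix as the canonical one
    stopifnot(max(abs(v$E - logcpm)) < 1e-8)
  }

  structure(
    list(logcpm = logcpm, weights = weights,
         norm_factors = setNames(as.numeric(factors), counts$sample_ids),
         library_sizes = counts$library_sizes, design = design, span = span),
    class = "voom_norm"
  )
}

#' @export
print.voom_norm <- function(x, ...) {
  cat(sprintf("<voom_norm> %d miRNAs x %d libraries; weight range [%.3g, %.3g]\n",
              nrow(x$logcpm), ncol(x$logcpm), min(x$weights), max(x$weights)))
  invisible(x)
}

#' @rdname voom_transform
#' @param x A `voom_norm` object.
#' @param ... Unused.
#' @method tidy voom_norm
#' @export
tidy.voom_norm <- function(x, ...) {
  as_tibble(as.data.frame.table(x$logcpm, responseName = "logcpm",
                                stringsAsFactors = FALSE)) |>
    dplyr::rename(mirna = "Var1", sample = "Var2") |>
    dplyr::mutate(weight = as.vector(x$weights))
}
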