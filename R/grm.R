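#' Genomic relationship matrix from SNP dosages
#'
#' Standardizes each marker column (centered by its mean, scaled to unit
#' variance, or by `sqrt(2p(1-p))` with `scale = "2pq"`), divides by
#' `sqrt(n_markers)` so the average diagonal of `G = Z Z'` is about 1, and
#' forms `G`. Monomorphic markers carry no information and are dropped with a
#' warning.
#'
#' @param dosages Samples x markers numeric matrix with entries in \{0, 1, 2\}
#'   (fractional values from mean imputation are accepted).
#' @param scale `"observed"` (unit observed-genotype variance, the default) or
#'   `"2pq"` (binomial variance from the allele frequency).
#' @return An object of class `"genomic_relationship"`: list with `Z`
#'   (samples x markers standardized dosages), `G` (samples x samples),
#'   `marker_ids`, `sample_ids`, and the per-marker `center`/`scale` record.
#' @export
build_grm <- function(dosages, scale = c("observed", "2pq")) {
  scale <- match.arg(scale)
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages))) {
    colnames(dosages) <- sprintf("M%05d", seq_len(ncol(dosages)))
  }
  if (is.null(rownames(dosages))) {
    rownames(dosages) <- sprintf("S%04d", seq_len(nrow(dosages)))
  }
  v <- apply(dosages, 2, var)
  mono <- v == 0 | !is.finite(v)
  if (all(mono)) {
    abort("all markers are monomorphic", class = "mireqtl_input_error")
  }
  if (any(mono)) {
    warn(sprintf("dropping %d monomorphic marker(s)", sum(mono)))
    dosages <- dosages[, !mono, drop = FALSE]
    v <- v[!mono]
  }
  ctr <- colMeans(dosages)
  scl <- if (scale == "observed") {
    sqrt(v)
  } else {
    p <- ctr / 2
    sqrt(2 * p * (1 - p))
  }
  m <- ncol(dosages)
  Z <- sweep(sweep(dosages, 2, ctr), 2, scl * sqrt(m), `/`)
  G <- tcrossprod(Z)
  structure(
    list(Z = Z, G = G,
         marker_ids = colnames(dosages), sample_ids = rownames(dosages),
         center = ctr, scale = scl * sqrt(m), scale_method = scale),
    class = "genomic_relationship"
  )
}

#' @export
print.genomic_relationship <- function(x, ...) {
  cat(sprintf("<genomic_relationship> %d samples, %d markers; mean diag(G) = %.3f\n",
              nrow(x$G), length(x$marker_ids), mean(diag(x$G))))
  invisible(x)
}
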