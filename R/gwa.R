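#' Backsolve per-SNP effects from predicted breeding values
#'
#' Transforms a GBLUP fit's breeding values into marker effects
#' `g_hat = Z' G^-1 a_hat` with variances
#' `var(g_hat) = diag(Z' G^-1 var(a_hat) G^-1 Z)` and standardized statistics
#' `t_j = g_hat_j / sqrt(var(g_hat_j))`. Because
#' `a_hat = sigma_a^2 G P y` lies in the range of `G = Z Z'`, these equal
#' `sigma_a^2 Z' P y` and `sigma_a^4 diag(Z' P Z)` for any (pseudo-)inverse of
#' `G`, which is how they are computed — no explicit inversion, and singular
#' `G` is handled for free. Two-sided p-values use a standard-normal reference
#' for `t` (or Student's t with `n - rank(X) - 1` df via `p_reference = "t"`).
#'
#' @param fit A [fit_gblup()] object.
#' @param grm The [build_grm()] object the fit's `G` came from.
#' @param p_reference `"normal"` (default) or `"t"`.
#' @return Tibble: `mirna`, `marker_id`, `g_hat`, `var_g_hat`, `t`, `p`.
#'   If the fit's additive variance is zero there is no signal to backsolve:
#'   all effects and statistics are 0 (p = 1) and a warning is raised.
#' @export
backsolve_snp_effects <- function(fit, grm, p_reference = c("normal", "t")) {
  stopifnot(inherits(fit, "gblup_fit"), inherits(grm, "genomic_relationship"))
  p_reference <- match.arg(p_reference)
  m <- length(grm$marker_ids)
  if (fit$sigma2_a <= 0) {
    warn("additive variance is zero; all SNP effects are 0")
    return(tibble(mirna = fit$mirna, marker_id = grm$marker_ids,
                  g_hat = 0, var_g_hat = 0, t = 0, p = 1))
  }
  g <- fit$sigma2_a * as.numeric(crossprod(grm$Z, fit$Py))
  PZ <- fit$P %*% grm$Z
  var_g <- pmax(fit$sigma2_a^2 * colSums(grm$Z * PZ), 0)
  t_stat <- ifelse(var_g > 0, g / sqrt(var_g), 0)
  p <- if (p_reference == "normal") {
    2 * pnorm(-abs(t_stat))
  } else {
    2 * pt(-abs(t_stat), df = fit$n - fit$rank_X - 1)
  }
  tibble(mirna = fit$mirna, marker_id = grm$marker_ids,
         g_hat = g, var_g_hat = var_g, t = t_stat, p = p)
}

#' Genome-wide association scan across miRNAs
#'
#' Backsolves SNP effects for every fit, attaches marker coordinates, and
#' adjusts p-values jointly across all (miRNA, SNP) tests — the multiple-
#' testing universe in which "N significant miRNA-SNP associations" is a
#' single tally. Per-miRNA adjustment is available with
#' `universe = "per_mirna"`.
#'
#' @param fits List of `gblup_fit` objects (or a single fit).
#' @param grm A [build_grm()] object.
#' @param map Marker map tibble with columns `marker`, `chrom`, `pos`.
#' @param method `"BH"` or `"storey"`.
#' @param universe `"joint"` (default) or `"per_mirna"`.
#' @param p_reference Passed to [backsolve_snp_effects()].
#' @return Tibble: `mirna`, `marker_id`, `chrom`, `pos`, `g_hat`, `var_g_hat`,
#'   `t`, `p`, `q`.
#' @export
gwa_scan <- function(fits, grm, map, method = c("BH", "storey"),
                     universe = c("joint", "per_mirna"),
                     p_reference = c("normal", "t")) {
  method <- match.arg(method)
  universe <- match.arg(universe)
  if (inherits(fits, "gblup_fit")) fits <- list(fits)
  assoc <- purrr::map_dfr(fits, backsolve_snp_effects, grm = grm,
                          p_reference = p_reference)
  assoc <- dplyr::left_join(assoc, dplyr::select(map, "marker", "chrom", "pos"),
                            by = c(marker_id = "marker"))
  assoc <- dplyr::relocate(assoc, "chrom", "pos", .after = "marker_id")
  if (universe == "joint") {
    assoc$q <- adjust_pvalues(assoc$p, ifelse(method == "BH", "BH", "storey"))
  } else {
    assoc <- dplyr::mutate(
      dplyr::group_by(assoc, .data$mirna),
      q = adjust_pvalues(.data$p, ifelse(method == "BH", "BH", "storey"))
    ) |> dplyr::ungroup()
  }
  assoc
}

#' Assemble significant SNPs into eQTL peaks
#'
#' Significant SNPs (`q < fdr`) for one miRNA are grouped per chromosome;
#' consecutive significant SNPs whose positions lie within `merge_gap_bp` of
#' their nearest significant neighbour join one peak. The peak SNP is the
#' member with minimum p (ties broken by smaller position) and the peak range
#' spans the member positions (width 0 for single-SNP peaks).
#'
#' @param results Association tibble from [gwa_scan()] (needs `mirna`,
#'   `marker_id`, `chrom`, `pos`, `p`, `q`).
#' @param fdr Significance threshold on q.
#' @param merge_gap_bp Maximum gap (bp) between adjacent significant SNPs in
#'   one peak. The default, 20 Mb, keeps same-chromosome signals tens of
#'   megabases apart as separate peaks while absorbing LD-sized gaps.
#' @return Tibble, one row per peak: `mirna`, `chrom`, `peak_snp`, `peak_pos`,
#'   `peak_p`, `peak_q`, `start`, `end`, `width_bp`, `n_snps`, `snp_ids`
#'   (list-column). Empty (zero rows) when nothing is significant.
#' @export
call_peaks <- function(results, fdr = 0.05, merge_gap_bp = 20e6) {
  check_scalar_number(fdr, "fdr", 0, 1)
  check_scalar_number(merge_gap_bp, "merge_gap_bp", 0)
  sig <- dplyr::filter(results, .data$q < fdr)
  if (nrow(sig) == 0) {
    return(empty_peaks())
  }
  sig |>
    dplyr::group_by(.data$mirna, .data$chrom) |>
    dplyr::arrange(.data$pos, .by_group = TRUE) |>
    dplyr::mutate(cluster = cumsum(c(0, diff(.data$pos) > merge_gap_bp))) |>
    dplyr::group_by(.data$mirna, .data$chrom, .data$cluster) |>
    dplyr::summarise(
      peak_snp = .data$marker_id[order(.data$p, .data$pos)][1],
      peak_pos = .data$pos[order(.data$p, .data$pos)][1],
      peak_p = min(.data$p),
      peak_q = .data$q[order(.data$p, .data$pos)][1],
      start = min(.data$pos), end = max(.data$pos),
      width_bp = max(.data$pos) - min(.data$pos),
      n_snps = dplyr::n(),
      snp_ids = list(.data$marker_id),
      .groups = "drop"
    ) |>
    dplyr::select(-"cluster") |>
    dplyr::arrange(.data$mirna, .data$chrom, .data$start)
}

empty_peaks <- function() {
  tibble(mirna = character(), chrom = integer(),
         peak_snp = character(), peak_pos = numeric(),
         peak_p = numeric(), peak_q = numeric(),
         start = numeric(), end = numeric(), width_bp = numeric(),
         n_snps = integer(), snp_ids = list())
}

#' Classify eQTL peaks as local or distant regulators
#'
#' A peak is a `local` regulator iff it lies on the same chromosome as the
#' miRNA precursor transcript and its range (a point for single-SNP peaks)
#' overlaps the precursor interval under closed-interval arithmetic; otherwise
#' `distant`. Peaks of miRNAs whose precursor maps to an unplaced scaffold
#' (`NA` chromosome, or absent from the annotation) are `unplaced`.
#'
#' @param peaks Peak tibble from [call_peaks()].
#' @param precursors Tibble with columns `mirna`, `chrom`, `start`, `end`
#'   (1-based inclusive; `NA` chrom for unplaced scaffolds).
#' @return `peaks` with `regulation` and precursor coordinate columns added.
#' @export
classify_regulation <- function(peaks, precursors) {
  prec <- dplyr::select(precursors, "mirna", prec_chrom = "chrom",
                        prec_start = "start", prec_end = "end")
  dplyr::left_join(peaks, prec, by = "mirna") |>
    dplyr::mutate(
      regulation = dplyr::case_when(
        is.na(.data$prec_chrom) ~ "unplaced",
        .data$chrom == .data$prec_chrom &
          .data$start <= .data$prec_end &
          .data$end >= .data$prec_start ~ "local",
        TRUE ~ "distant"
      )
    )
}
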