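# TSV/BED readers and writers. Internal convention: coordinates are 1-based
# inclusive; BED output is 0-based half-open. Reals are written at 12
# significant digits so files round-trip at documented precision.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", formatC(x, digits = 12, format = "g"))
}

write_matrix_tsv <- function(mat, path, id_col = "id") {
  df <- as.data.frame(mat, check.names = FALSE)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], fmt_num)
  out <- dplyr::bind_cols(setNames(tibble(rownames(mat)), id_col),
                          as_tibble(df))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

read_matrix_tsv <- function(path, id_col = 1L) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  m <- as.matrix(df[-id_col])
  rownames(m) <- as.character(df[[id_col]])
  m
}

#' Read and write miRNA count matrices
#'
#' Counts are stored as TSV with miRNA ids in the first column and one column
#' per sample library.
#'
#' @param path File path.
#' @param library_sizes Optional library sizes for [read_count_matrix()]
#'   (defaults to column sums).
#' @return `read_count_matrix()` returns a [count_matrix()];
#'   `write_count_matrix()` returns the path invisibly.
#' @export
read_count_matrix <- function(path, library_sizes = NULL) {
  m <- read_matrix_tsv(path)
  storage.mode(m) <- "integer"
  count_matrix(m, library_sizes = library_sizes)
}

#' @rdname read_count_matrix
#' @param counts A [count_matrix()].
#' @export
write_count_matrix <- function(counts, path) {
  stopifnot(inherits(counts, "count_matrix"))
  write_matrix_tsv(counts$counts, path, id_col = "mirna")
}

#' Read a SNP dosage matrix, validating and mean-imputing entries
#'
#' Expects a TSV with sample ids in the first column and a header row of
#' marker ids (the layout written by [write_dosage_matrix()], PLINK-raw-like).
#' Entries must be 0, 1, 2 or missing (`NA`/empty); anything else is a parse
#' error naming the offending row and column. Missing entries are imputed to
#' the per-marker mean and the imputation count is reported and attached as
#' attribute `n_imputed`.
#'
#' @param path File path.
#' @return Samples x markers numeric matrix with dimnames.
#' @export
read_dosage_matrix <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  ids <- df[[1]]
  raw <- as.matrix(df[-1])
  num <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  is_na <- raw %in% c("NA", "", "NaN") | is.na(raw)
  bad <- which(is.na(num) & !is_na, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf("non-numeric dosage at row %d, column '%s'",
                  bad[1, 1], colnames(raw)[bad[1, 2]]),
          class = "mireqtl_parse_error")
  }
  ok <- num %in% c(0, 1, 2) | is.na(num)
  dim(ok) <- dim(num)
  if (!all(ok)) {
    off <- which(!ok, arr.ind = TRUE)[1, ]
    abort(sprintf("dosage not in {0,1,2} at row %d, column '%s'",
                  off[1], colnames(raw)[off[2]]),
          class = "mireqtl_parse_error")
  }
  n_imputed <- sum(is_na)
  if (n_imputed > 0) {
    cm <- colMeans(num, na.rm = TRUE)
    idx <- which(is.na(num), arr.ind = TRUE)
    num[idx] <- cm[idx[, 2]]
    inform(sprintf("imputed %d missing dosage(s) to per-marker means", n_imputed))
  }
  dimnames(num) <- list(ids, colnames(raw))
  attr(num, "n_imputed") <- n_imputed
  num
}

#' @rdname read_dosage_matrix
#' @param dosages Samples x markers matrix.
#' @export
write_dosage_matrix <- function(dosages, path) {
  write_matrix_tsv(dosages, path, id_col = "sample")
}

#' Read and write the marker map
#'
#' Columns `marker`, `chrom`, `pos` (1-based bp) and any extras (e.g. `block`,
#' `maf`).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_marker_map <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_marker_map
#' @param map Marker map tibble.
#' @export
write_marker_map <- function(map, path) {
  readr::write_tsv(map, path, progress = FALSE)
  invisible(path)
}

#' Convert between 1-based inclusive intervals and BED
#'
#' Internal coordinates are 1-based inclusive; BED files are 0-based
#' half-open. `intervals_to_bed()` subtracts 1 from `start`;
#' `bed_to_intervals()` adds it back.
#'
#' @param x Tibble with columns `chrom`, `start`, `end` (plus a `name` column
#'   or any first extra column used as the BED name).
#' @return A tibble in the other convention.
#' @export
intervals_to_bed <- function(x) {
  extras <- setdiff(names(x), c("chrom", "start", "end"))
  nm <- if (length(extras) > 0) as.character(x[[extras[1]]]) else rep(".", nrow(x))
  tibble(chrom = x$chrom, start = x$start - 1, end = x$end, name = nm)
}

#' @rdname intervals_to_bed
#' @export
bed_to_intervals <- function(x) {
  tibble(chrom = x$chrom, start = x$start + 1, end = x$end,
         name = x$name %||% rep(".", nrow(x)))
}

#' @rdname intervals_to_bed
#' @param path File path.
#' @export
write_bed <- function(x, path) {
  bed <- intervals_to_bed(x)
  bed$chrom <- ifelse(is.na(bed$chrom), "unplaced", as.character(bed$chrom))
  readr::write_tsv(bed, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' @rdname intervals_to_bed
#' @export
read_bed <- function(path) {
  bed <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "name"),
                         show_col_types = FALSE, progress = FALSE)
  bed$chrom <- suppressWarnings(
    ifelse(bed$chrom == "unplaced", NA, bed$chrom))
  out <- bed_to_intervals(bed)
  out$chrom <- suppressWarnings(as.integer(out$chrom))
  out
}

#' Write a simulated study to disk
#'
#' Writes every input the analysis pipeline reads: counts TSV, dosage TSV,
#' marker map TSV, covariates TSV, precursor BED, and — when phenotypes/genes
#' were simulated — phenotype, gene-expression, gene-map and target-list
#' TSVs, plus a machine-readable JSON truth file with the planted values.
#'
#' @param sim Output of [simulate_eqtl_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_sim_data <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = write_count_matrix(sim$mirna$counts, file.path(dir, "counts.tsv")),
    dosages = write_dosage_matrix(sim$genotypes$dosages,
                                  file.path(dir, "dosages.tsv")),
    marker_map = write_marker_map(sim$genotypes$map,
                                  file.path(dir, "marker_map.tsv")),
    covariates = {
      readr::write_tsv(sim$covariates, file.path(dir, "covariates.tsv"),
                       progress = FALSE)
      file.path(dir, "covariates.tsv")
    },
    precursors = write_bed(
      dplyr::select(sim$mirna$precursors, "chrom", "start", "end", "mirna"),
      file.path(dir, "precursors.bed"))
  )
  if (ncol(sim$phenogene$phenotypes) > 1) {
    readr::write_tsv(sim$phenogene$phenotypes,
                     file.path(dir, "phenotypes.tsv"), progress = FALSE)
    paths["phenotypes"] <- file.path(dir, "phenotypes.tsv")
  }
  if (nrow(sim$phenogene$genes) > 0) {
    write_matrix_tsv(sim$phenogene$genes, file.path(dir, "genes.tsv"),
                     id_col = "gene")
    readr::write_tsv(sim$phenogene$gene_map, file.path(dir, "gene_map.tsv"),
                     progress = FALSE)
    readr::write_tsv(sim$phenogene$targets, file.path(dir, "targets.tsv"),
                     progress = FALSE)
    paths["genes"] <- file.path(dir, "genes.tsv")
    paths["gene_map"] <- file.path(dir, "gene_map.tsv")
    paths["targets"] <- file.path(dir, "targets.tsv")
  }
  truth <- sim$mirna$truth
  truth_small <- list(
    h2 = as.list(truth$h2),
    causal_plan = truth$causal_plan,
    pqtl_plan = sim$phenogene$truth$pqtl_plan,
    target_plan = sim$phenogene$truth$target_plan,
    library_sizes = as.list(truth$library_sizes),
    seed = sim$config$seed
  )
  jsonlite::write_json(truth_small, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths["truth"] <- file.path(dir, "truth.json")
  invisible(paths)
}
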