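#' Run configuration for the end-to-end pipeline
#'
#' Reads (or takes as a list) a YAML key-value configuration naming the input
#' files and thresholds of the analysis. Every threshold of the method is a
#' named key with its conventional default: `fdr` 0.05, `cpm_threshold` 1,
#' `min_fail_libraries` 44, `merge_gap_mb` 20, `voom_span` 0.5,
#' `fdr_method` "BH", `lrt_null` "mixture", `p_reference` "normal",
#' `universe` "joint", `grm_scale` "observed". Referenced input paths must
#' exist at validation time.
#'
#' @param config Path to a YAML file, or a named list.
#' @return Validated list of class `"run_config"`.
#' @export
run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(
    fdr = 0.05, cpm_threshold = 1, min_fail_libraries = 44,
    merge_gap_mb = 20, voom_span = 0.5, fdr_method = "BH",
    lrt_null = "mixture", p_reference = "normal", universe = "joint",
    grm_scale = "observed", out_dir = "mireqtl_out", seed = 1
  )
  cfg <- modifyList(defaults, config)
  check_scalar_number(cfg$fdr, "fdr", 0, 1)
  check_scalar_number(cfg$cpm_threshold, "cpm_threshold", 0)
  check_scalar_number(cfg$merge_gap_mb, "merge_gap_mb", 0)
  check_scalar_number(cfg$voom_span, "voom_span", 0.05, 1)
  required <- c("counts", "dosages", "marker_map", "covariates")
  for (key in required) {
    if (is.null(cfg[[key]])) {
      stop_bad_config(sprintf("config is missing required input path `%s`", key))
    }
  }
  paths <- c(required, "precursors", "pqtl", "targets", "genes", "gene_map",
             "phenotypes")
  for (key in paths) {
    if (!is.null(cfg[[key]]) && !file.exists(cfg[[key]])) {
      stop_bad_config(sprintf("config field `%s`: file not found: %s",
                              key, cfg[[key]]))
    }
  }
  structure(cfg, class = "run_config")
}

#' Run the analysis pipeline end to end
#'
#' Orchestrates normalize (filter, TMM, voom), GBLUP fitting with
#' heritability tests, the GWA backsolve with peak calling and local/distant
#' classification, conditional analysis of every peak SNP, and — when
#' pQTL/target/phenotype inputs are configured — colocalization and the
#' correlation layers. Each stage's outputs are written as TSV under
#' `out_dir`, with a JSON manifest recording parameters, record counts after
#' every filter, and md5 hashes of inputs and outputs. Reruns with identical
#' config reproduce identical result files.
#'
#' @param config A [run_config()] (or path/list coercible to one).
#' @param stages Character subset of
#'   `c("normalize", "fit", "gwa", "conditional", "colocalize")`; later stages
#'   always run their prerequisites.
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config,
                         stages = c("normalize", "fit", "gwa", "conditional",
                                    "colocalize")) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_counts <- list()
  outputs <- character()

  counts <- read_count_matrix(cfg$counts)
  dosages <- read_dosage_matrix(cfg$dosages)
  map <- read_marker_map(cfg$marker_map)
  covariates <- readr::read_tsv(cfg$covariates, show_col_types = FALSE,
                                progress = FALSE)
  log_counts$mirnas_in <- nrow(counts$counts)
  log_counts$markers_in <- ncol(dosages)

  # normalize
  filtered <- filter_low_expression(counts, cfg$cpm_threshold,
                                    cfg$min_fail_libraries)
  log_counts$mirnas_after_filter <- nrow(filtered$counts)
  inform(sprintf("expression filter: %d of %d miRNAs retained",
                 nrow(filtered$counts), nrow(counts$counts)))
  factors <- tmm_factors(filtered)
  design <- model.matrix(~ sex + growth_group, data = covariates)
  norm <- voom_transform(filtered, factors, design, span = cfg$voom_span)
  out <- list(counts = counts, filtered = filtered, factors = factors,
              norm = norm, covariates = covariates, map = map)
  write_matrix_tsv(norm$logcpm, file.path(cfg$out_dir, "logcpm.tsv"), "mirna")
  write_matrix_tsv(norm$weights, file.path(cfg$out_dir, "weights.tsv"), "mirna")
  readr::write_tsv(tibble(sample = names(factors), factor = fmt_num(factors)),
                   file.path(cfg$out_dir, "tmm_factors.tsv"), progress = FALSE)
  outputs <- c(outputs, file.path(cfg$out_dir,
                                  c("logcpm.tsv", "weights.tsv", "tmm_factors.tsv")))
  if (!any(c("fit", "gwa", "conditional", "colocalize") %in% stages)) {
    return(invisible(finish_manifest(cfg, out, outputs, log_counts)))
  }

  # fit
  grm <- build_grm(dosages, scale = cfg$grm_scale)
  fits <- fit_gblup_all(norm, grm, design, compute_se = TRUE)
  h2_table <- test_heritability(fits, fdr = cfg$fdr,
                                method = ifelse(cfg$fdr_method == "storey",
                                                "storey", "BH"),
                                null_dist = cfg$lrt_null)
  out$grm <- grm
  out$fits <- fits
  out$h2_table <- h2_table
  log_counts$mirnas_significant_h2 <- sum(h2_table$significant)
  readr::write_tsv(dplyr::mutate(h2_table,
                                 dplyr::across(dplyr::where(is.numeric), fmt_num)),
                   file.path(cfg$out_dir, "heritability.tsv"), progress = FALSE)
  outputs <- c(outputs, file.path(cfg$out_dir, "heritability.tsv"))
  if (!any(c("gwa", "conditional", "colocalize") %in% stages)) {
    return(invisible(finish_manifest(cfg, out, outputs, log_counts)))
  }

  # gwa
  assoc <- gwa_scan(fits, grm, map,
                    method = ifelse(cfg$fdr_method == "storey", "storey", "BH"),
                    universe = cfg$universe, p_reference = cfg$p_reference)
  peaks <- call_peaks(assoc, fdr = cfg$fdr,
                      merge_gap_bp = cfg$merge_gap_mb * 1e6)
  if (!is.null(cfg$precursors)) {
    prec <- read_bed(cfg$precursors)
    prec <- dplyr::rename(prec, mirna = "name")
    peaks <- classify_regulation(peaks, prec)
  }
  out$associations <- assoc
  out$peaks <- peaks
  log_counts$significant_associations <- sum(assoc$q < cfg$fdr)
  log_counts$eqtl_peaks <- nrow(peaks)
  inform(sprintf("GWA: %d significant associations in %d peak(s)",
                 sum(assoc$q < cfg$fdr), nrow(peaks)))
  readr::write_tsv(
    dplyr::mutate(dplyr::select(assoc, -dplyr::any_of("snp_ids")),
                  dplyr::across(dplyr::where(is.numeric), fmt_num)),
    file.path(cfg$out_dir, "associations.tsv"), progress = FALSE)
  peaks_flat <- dplyr::mutate(dplyr::select(peaks, -"snp_ids"),
                              dplyr::across(dplyr::where(is.numeric), fmt_num))
  readr::write_tsv(peaks_flat, file.path(cfg$out_dir, "peaks.tsv"),
                   progress = FALSE)
  if (nrow(peaks) > 0) {
    write_bed(dplyr::transmute(peaks, chrom = .data$chrom,
                               start = pmax(1, .data$start),
                               end = pmax(.data$end, .data$start),
                               name = paste0(.data$mirna, "@", .data$peak_snp)),
              file.path(cfg$out_dir, "peaks.bed"))
    outputs <- c(outputs, file.path(cfg$out_dir, "peaks.bed"))
  }
  outputs <- c(outputs, file.path(cfg$out_dir, c("associations.tsv", "peaks.tsv")))
  if (!any(c("conditional", "colocalize") %in% stages)) {
    return(invisible(finish_manifest(cfg, out, outputs, log_counts)))
  }

  # conditional analysis of every peak SNP
  cond <- purrr::pmap(peaks, function(mirna, peak_snp, ...) {
    orig <- dplyr::filter(peaks, .data$mirna == !!mirna)
    conditional_fit(fits[[mirna]], dosages[, peak_snp], peak_snp, grm, map,
                    fdr = cfg$fdr, merge_gap_bp = cfg$merge_gap_mb * 1e6,
                    original_peaks = orig)
  })
  cond_table <- purrr::map_dfr(cond, tidy)
  out$conditional <- cond
  out$conditional_table <- cond_table
  if (nrow(cond_table) > 0) {
    readr::write_tsv(dplyr::mutate(cond_table,
                                   dplyr::across(dplyr::where(is.numeric), fmt_num)),
                     file.path(cfg$out_dir, "conditional.tsv"), progress = FALSE)
    outputs <- c(outputs, file.path(cfg$out_dir, "conditional.tsv"))
  }
  if (!("colocalize" %in% stages)) {
    return(invisible(finish_manifest(cfg, out, outputs, log_counts)))
  }

  # colocalization + correlation layers (only with the optional inputs)
  if (!is.null(cfg$pqtl)) {
    pqtl <- readr::read_tsv(cfg$pqtl, show_col_types = FALSE, progress = FALSE)
    if ("range_start" %in% names(pqtl)) {
      pqtl <- dplyr::rename(pqtl, start = "range_start", end = "range_end")
    }
    events <- overlap_events(peaks, pqtl)
    out$events <- events
    log_counts$colocalization_events <- nrow(events)
    readr::write_tsv(events, file.path(cfg$out_dir, "colocalization_events.tsv"),
                     progress = FALSE)
    outputs <- c(outputs, file.path(cfg$out_dir, "colocalization_events.tsv"))
  }
  if (!is.null(cfg$targets) && !is.null(cfg$genes)) {
    targets <- readr::read_tsv(cfg$targets, show_col_types = FALSE,
                               progress = FALSE)
    genes <- read_matrix_tsv(cfg$genes)
    mirna_resid <- correct_expression_all(fits)
    gene_fits <- lapply(rownames(genes), function(g) {
      fit_gblup(genes[g, colnames(mirna_resid)], design, grm$G, mirna = g)
    })
    names(gene_fits) <- rownames(genes)
    gene_resid <- correct_expression_all(gene_fits)
    targets <- dplyr::filter(targets, .data$mirna %in% rownames(mirna_resid),
                             .data$gene %in% rownames(gene_resid))
    tau_tbl <- mirna_target_correlation(mirna_resid, gene_resid, targets,
                                        fdr = cfg$fdr)
    out$target_correlations <- tau_tbl
    log_counts$retained_targets <- sum(tau_tbl$retained, na.rm = TRUE)
    readr::write_tsv(dplyr::mutate(tau_tbl,
                                   dplyr::across(dplyr::where(is.numeric), fmt_num)),
                     file.path(cfg$out_dir, "target_correlations.tsv"),
                     progress = FALSE)
    outputs <- c(outputs, file.path(cfg$out_dir, "target_correlations.tsv"))
    if (!is.null(cfg$phenotypes)) {
      phen <- readr::read_tsv(cfg$phenotypes, show_col_types = FALSE,
                              progress = FALSE)
      pheno_resid <- correct_phenotypes(phen, covariates)
      gene_pheno <- gene_phenotype_correlation(gene_resid, pheno_resid)
      mirna_pheno <- gene_phenotype_correlation(mirna_resid, pheno_resid)
      interest <- targets_of_interest(tau_tbl, gene_pheno, mirna_pheno,
                                      fdr = cfg$fdr)
      out$targets_of_interest <- interest
      readr::write_tsv(dplyr::mutate(interest,
                                     dplyr::across(dplyr::where(is.numeric), fmt_num)),
                       file.path(cfg$out_dir, "targets_of_interest.tsv"),
                       progress = FALSE)
      outputs <- c(outputs, file.path(cfg$out_dir, "targets_of_interest.tsv"))
    }
  }
  invisible(finish_manifest(cfg, out, outputs, log_counts))
}

finish_manifest <- function(cfg, out, outputs, log_counts) {
  inputs <- unlist(cfg[c("counts", "dosages", "marker_map", "covariates",
                         "precursors", "pqtl", "targets", "genes",
                         "phenotypes")])
  inputs <- inputs[!is.na(inputs) & file.exists(inputs)]
  manifest <- list(
    package_version = as.character(utils::packageVersion("mireqtl")),
    parameters = unclass(cfg),
    record_counts = log_counts,
    input_md5 = as.list(tools::md5sum(inputs)),
    output_md5 = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       force = TRUE)
  out$manifest <- manifest
  out
}

#' Command-line entry point
#'
#' Thin argument dispatcher used by the `inst/cli/mireqtl.R` script:
#' `simulate --config <yaml> --out-dir <dir> --seed <int>` writes a synthetic
#' study; `run --config <yaml> [--stages normalize,fit,gwa,conditional,colocalize]`
#' runs the analysis pipeline. All heavy lifting is in the exported functions.
#'
#' @param args Character vector of command-line arguments
#'   (e.g. `commandArgs(trailingOnly = TRUE)`).
#' @return The stage result, invisibly.
#' @export
mireqtl_cli <- function(args) {
  if (length(args) == 0) {
    abort("usage: mireqtl <simulate|run> --config <file> [options]",
          class = "mireqtl_cli_error")
  }
  cmd <- args[1]
  opts <- parse_cli_args(args[-1])
  if (is.null(opts$config)) {
    abort("--config is required", class = "mireqtl_cli_error")
  }
  switch(
    cmd,
    simulate = {
      raw <- yaml::read_yaml(opts$config)
      if (!is.null(opts$seed)) raw$seed <- as.integer(opts$seed)
      cfg <- do.call(sim_config, raw[intersect(names(raw),
                                               names(formals(sim_config)))])
      sim <- simulate_eqtl_study(cfg)
      invisible(write_sim_data(sim, opts$`out-dir` %||% "sim_out"))
    },
    run = {
      stages <- if (is.null(opts$stages)) {
        c("normalize", "fit", "gwa", "conditional", "colocalize")
      } else {
        strsplit(opts$stages, ",")[[1]]
      }
      run_pipeline(run_config(opts$config), stages = stages)
    },
    abort(sprintf("unknown subcommand '%s'", cmd), class = "mireqtl_cli_error")
  )
}

parse_cli_args <- function(args) {
  opts <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--")) {
      abort(sprintf("unexpected argument '%s'", a), class = "mireqtl_cli_error")
    }
    key <- substring(a, 3)
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1
    } else {
      opts[[key]] <- args[i + 1]
      i <- i + 2
    }
  }
  opts
}
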