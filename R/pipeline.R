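#' Configure an end-to-end analysis run
#'
#' Collects input locations (or a synthetic-data configuration), tissue names
#' and library sizes, every analysis threshold, the seed, and the output
#' directory. All thresholds default to the values used throughout the
#' package: e-value cutoff 1e-10, minimum 4 reads, TPM floor 2, splice gap
#' 15 bases, extreme-set size 500, significance level 0.05.
#'
#' @param counts,alignments,annotation,contaminants Input file paths (contig
#'   count TSV, tabular BLAST file, annotation TSV, contaminant subject-id
#'   list); all may be omitted when `synthetic` is given.
#' @param library_sizes Named vector of reads per library (required for file
#'   inputs; taken from the synthetic config otherwise).
#' @param synthetic Optional [simulation_config()]: generate inputs instead of
#'   reading files.
#' @param evalue_cutoff,min_reads,floor_tpm,min_gap,top_k,alpha Thresholds.
#' @param n_boot Bootstrap resamples for the per-tissue summary.
#' @param seed Integer seed for all stochastic stages.
#' @param out_dir Output directory.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(counts = NULL, alignments = NULL,
                            annotation = NULL, contaminants = NULL,
                            library_sizes = NULL, synthetic = NULL,
                            evalue_cutoff = 1e-10, min_reads = 4,
                            floor_tpm = 2, min_gap = 15, top_k = 500,
                            alpha = 0.05, n_boot = 10000,
                            seed = 1L, out_dir = tempfile("taudge_run_")) {
  if (is.null(synthetic)) {
    for (f in c(counts, alignments, annotation)) {
      if (is.null(f) || !file.exists(f)) {
        abort("file inputs (counts, alignments, annotation) are required unless `synthetic` is given")
      }
    }
    if (is.null(library_sizes)) abort("library_sizes required for file inputs")
  } else {
    stopifnot(inherits(synthetic, "simulation_config"))
    library_sizes <- library_sizes %||% synthetic$library_sizes
  }
  thresholds <- list(evalue_cutoff = evalue_cutoff, min_reads = min_reads,
                     floor_tpm = floor_tpm, min_gap = min_gap, top_k = top_k,
                     alpha = alpha, n_boot = n_boot)
  if (any(unlist(thresholds) <= 0)) abort("all thresholds must be positive")
  if (anyDuplicated(names(library_sizes))) abort("tissue names must be unique")
  structure(
    list(counts = counts, alignments = alignments, annotation = annotation,
         contaminants = contaminants, library_sizes = library_sizes,
         synthetic = synthetic, thresholds = thresholds,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [pipeline_config()]; a `synthetic`
#' block, if present, is passed to [simulation_config()].
#'
#' @param path YAML file path.
#' @return A `pipeline_config` list.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$library_sizes)) y$library_sizes <- unlist(y$library_sizes)
  if (!is.null(y$synthetic)) {
    if (!is.null(y$synthetic$library_sizes)) {
      y$synthetic$library_sizes <- unlist(y$synthetic$library_sizes)
    }
    y$synthetic <- do.call(simulation_config, y$synthetic)
  }
  do.call(pipeline_config, y)
}

pipeline_stage <- function(name, expr) {
  message("[taudge] stage: ", name)
  tryCatch(expr, error = function(e) {
    abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full analysis pipeline
#'
#' Orchestrates mapping (alignment parsing, best-hit selection, contaminant
#' removal, coverage, splice-gap flags), quantification (gene aggregation,
#' TPM), specificity (tau table at contig and gene level), the resampling
#' null for sampling bias in tau, and the enrichment and statistical analyses
#' (tau-extreme and per-tissue GO overrepresentation, tau--omega and
#' length--expression correlations, group comparisons, per-tissue summary).
#' All module outputs are written as TSV/JSON under `config$out_dir`, together
#' with a manifest recording package version, seed, thresholds, input
#' checksums and per-stage record counts, so every reported number is
#' reproducible from config plus seed alone.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with all intermediate and final tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  th <- config$thresholds
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(f) file.path(config$out_dir, f)
  log_counts <- list()

  inputs <- pipeline_stage("input", {
    if (!is.null(config$synthetic)) {
      sim <- simulate_dge(config$synthetic)
      fixture_dir <- outp("synthetic_inputs")
      write_fixture_bundle(sim, fixture_dir)
      list(
        contigs = sim$contigs,
        alignments = file.path(fixture_dir, "alignments.tsv"),
        annotation = sim$catalog$annotation,
        contaminant_subjects = sim$contaminant_subjects,
        truth = sim$catalog$truth
      )
    } else {
      list(
        contigs = readr::read_tsv(config$counts, show_col_types = FALSE),
        alignments = config$alignments,
        annotation = readr::read_tsv(config$annotation, show_col_types = FALSE),
        contaminant_subjects = if (is.null(config$contaminants)) character()
                               else readLines(config$contaminants),
        truth = NULL
      )
    }
  })

  mapping <- pipeline_stage("mapping", {
    hits <- read_blast_tabular(inputs$alignments,
                               evalue_cutoff = th$evalue_cutoff)
    best <- select_best_hits(hits)
    part <- flag_contaminants(best, inputs$contaminant_subjects)
    log_counts$hits <- nrow(hits)
    log_counts$contigs_assigned <- nrow(part$assignments)
    log_counts$contigs_removed_contaminant <- nrow(part$removed)
    message("[taudge]   ", nrow(part$removed),
            " contig(s) removed as contaminants")
    splice <- flag_splice_gaps(
      semi_join(hits, part$assignments,
                by = c(qseqid = "contig_id", sseqid = "gene_id")),
      min_gap = th$min_gap
    )
    coverage <- summarize_gene_coverage(
      part$assignments,
      inputs$contigs |> select("contig_id", "length"),
      inputs$annotation |> select("gene_id", "length_bp")
    )
    readr::write_tsv(part$assignments, outp("assignments.tsv"))
    readr::write_tsv(part$removed, outp("contaminants_removed.tsv"))
    readr::write_tsv(splice, outp("splice_flags.tsv"))
    readr::write_tsv(coverage, outp("gene_coverage.tsv"))
    list(assignments = part$assignments, removed = part$removed,
         splice = splice, coverage = coverage)
  })

  quant <- pipeline_stage("quantification", {
    clean_contigs <- inputs$contigs |>
      filter(!.data$contig_id %in% mapping$removed$contig_id)
    gene_counts <- aggregate_contigs_to_genes(clean_contigs,
                                              mapping$assignments)
    gene_tpm <- compute_tpm(gene_counts, config$library_sizes)
    readr::write_tsv(gene_counts, outp("gene_counts.tsv"))
    readr::write_tsv(gene_tpm, outp("gene_tpm.tsv"))
    log_counts$genes_detected <- sum(gene_counts$gene_id != "<unannotated>")
    list(contigs = clean_contigs, gene_counts = gene_counts,
         gene_tpm = gene_tpm)
  })

  spec <- pipeline_stage("specificity", {
    annotated <- quant$gene_counts |> filter(.data$gene_id != "<unannotated>")
    gene_tau <- tau_table(annotated, config$library_sizes,
                          min_reads = th$min_reads, floor_tpm = th$floor_tpm)
    contig_tau <- tau_table(quant$contigs |> select(-"length"),
                            config$library_sizes,
                            min_reads = th$min_reads,
                            floor_tpm = th$floor_tpm)
    log_counts$genes_with_tau <- sum(!is.na(gene_tau$tau))
    readr::write_tsv(format_tau_tsv(gene_tau), outp("gene_tau.tsv"))
    readr::write_tsv(format_tau_tsv(contig_tau), outp("contig_tau.tsv"))
    list(gene_tau = gene_tau, contig_tau = contig_tau)
  })

  bias <- pipeline_stage("bias_simulation", {
    bs <- simulate_correlation_distribution(
      quant$contigs |> select(-"length"), config$library_sizes,
      seed = config$seed + 10L, min_reads = th$min_reads,
      floor_tpm = th$floor_tpm
    )
    jsonlite::write_json(
      list(observed_r = bs$observed$estimate, observed_df = bs$observed$df,
           simulated_r = bs$simulated_r,
           mean_simulated_r = bs$comparison$mean_simulated_r,
           t_statistic = bs$comparison$t_statistic, df = bs$comparison$df,
           p_value = bs$comparison$p_value, method = bs$comparison$method,
           mode = bs$mode, seed = config$seed + 10L),
      outp("bias_simulation.json"), auto_unbox = TRUE, digits = NA
    )
    bs
  })

  stats_out <- pipeline_stage("enrichment_statistics", {
    gene_tau <- spec$gene_tau
    universe <- gene_tau |> filter(!is.na(.data$tau)) |> pull("entity_id")
    k <- min(th$top_k, floor(length(universe) / 2))
    enr <- list()
    if (k >= 1) {
      sets <- select_tau_extreme_sets(gene_tau, k = k)
      enr$high_tau <- go_overrepresentation(sets$high_tau, universe,
                                            inputs$annotation,
                                            alpha = th$alpha)
      enr$low_tau <- go_overrepresentation(sets$low_tau, universe,
                                           inputs$annotation,
                                           alpha = th$alpha)
      readr::write_tsv(enr$high_tau, outp("enrichment_high_tau.tsv"))
      readr::write_tsv(enr$low_tau, outp("enrichment_low_tau.tsv"))
    }
    for (tis in unique(stats::na.omit(gene_tau$max_tissue))) {
      set <- gene_tau |>
        filter(!is.na(.data$tau), .data$max_tissue == tis) |>
        pull("entity_id")
      if (length(set) >= 1) {
        res <- go_overrepresentation(set, universe, inputs$annotation,
                                     alpha = th$alpha)
        readr::write_tsv(res, outp(paste0("enrichment_max_", tis, ".tsv")))
        enr[[paste0("max_", tis)]] <- res
      }
    }
    merged <- gene_tau |>
      filter(!is.na(.data$tau)) |>
      inner_join(inputs$annotation, by = c(entity_id = "gene_id"))
    correlations <- bind_rows(
      tau_vs_omega = correlate(merged, "tau", "omega", method = "spearman"),
      total_vs_omega = correlate(merged, "total_reads", "omega",
                                 method = "spearman", transform_x = "log10"),
      length_vs_total = correlate(merged, "length_bp", "total_reads",
                                  method = "spearman"),
      length_vs_tau = correlate(merged, "length_bp", "tau",
                                method = "spearman"),
      .id = "analysis"
    )
    groups <- bind_rows(
      omega_by_tissue = group_compare(merged, "omega", "max_tissue",
                                      method = "kruskal"),
      tau_by_tissue = group_compare(merged, "tau", "max_tissue",
                                    method = "anova"),
      .id = "analysis"
    )
    tissue_summary <- summarize_by_max_tissue(
      gene_tau, inputs$annotation,
      counts = quant$gene_counts |> filter(.data$gene_id != "<unannotated>"),
      n_boot = th$n_boot, seed = config$seed + 20L
    )
    readr::write_tsv(correlations, outp("correlations.tsv"))
    readr::write_tsv(groups, outp("group_comparisons.tsv"))
    readr::write_tsv(tissue_summary, outp("tissue_summary.tsv"))
    list(enrichment = enr, correlations = correlations, groups = groups,
         tissue_summary = tissue_summary)
  })

  manifest <- pipeline_stage("manifest", {
    input_files <- unlist(list(
      counts = config$counts, alignments = config$alignments,
      annotation = config$annotation, contaminants = config$contaminants
    ))
    if (is.null(input_files)) input_files <- character(0)
    man <- list(
      package = "taudge",
      version = as.character(utils::packageVersion("taudge")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$seed,
      thresholds = th,
      library_sizes = as.list(config$library_sizes),
      synthetic = !is.null(config$synthetic),
      input_md5 = as.list(tools::md5sum(input_files[!is.na(input_files)])),
      counts = log_counts
    )
    jsonlite::write_json(man, outp("manifest.json"), auto_unbox = TRUE,
                         digits = NA)
    man
  })

  invisible(list(config = config, inputs = inputs, mapping = mapping,
                 quantification = quant, specificity = spec, bias = bias,
                 statistics = stats_out, manifest = manifest))
}

format_tau_tsv <- function(tau_tbl) {
  tau_tbl |>
    mutate(tau = ifelse(is.na(.data$tau), "-", sprintf("%.3f", .data$tau)))
}
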