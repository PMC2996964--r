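#' Configure the multi-tissue digital-expression simulator
#'
#' Builds a validated configuration for the synthetic-data generator. The
#' defaults emulate a 454-era multi-tissue cDNA study: six tissues sequenced to
#' 0.25--0.4 million reads each, roughly twelve thousand detectable genes,
#' heavily skewed per-gene abundances, tissue profiles spanning
#' housekeeping-like (tau near 0.15) to single-tissue (tau above 0.8)
#' expression with a bimodal specificity distribution, a small contaminant
#' contig fraction, and a positive coupling between specificity and the
#' dN/dS ratio omega.
#'
#' @param n_genes Number of genes to simulate.
#' @param n_tissues Number of tissues/libraries.
#' @param library_sizes Named (or ordered) integer vector of reads per library;
#'   length `n_tissues`. Defaults to the six 454 library sizes of the
#'   motivating study.
#' @param profile_concentration Dirichlet concentration alpha controlling how
#'   tissue-specific the true expression profiles are. A scalar gives a single
#'   symmetric Dirichlet; a length-2 vector gives a two-component mixture
#'   (specific + broad), mixed according to `mixture_prop`.
#' @param mixture_prop Mixture weights when `profile_concentration` has two
#'   components; must sum to 1.
#' @param mean_expression_dispersion Log-normal sdlog of per-gene abundance;
#'   larger values give more skewed read-depth distributions.
#' @param contigs_per_gene_mean Poisson mean of the number of *extra* contig
#'   fragments per gene (each gene always yields at least one contig). Zero
#'   gives exactly one contig per expressed gene.
#' @param contaminant_fraction Fraction of contigs that are contaminants
#'   (foreign-organism sequence), in `[0, 1)`.
#' @param omega_coupling Slope linking true tau to simulated omega on the log
#'   scale: `omega = exp(log(0.15) + omega_coupling * tau + N(0, 0.7)) - 0.02`,
#'   clipped at zero. Positive values plant a positive tau--omega correlation.
#' @param abundance_tau_coupling Rank coupling (Gaussian copula) between log
#'   abundance and true tau; negative values make highly expressed genes less
#'   tissue specific, as observed in real transcriptomes. Default 0 (none).
#' @param seed Integer seed; all generator randomness derives from it.
#'
#' @return A `simulation_config` list.
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 200, seed = 1)
#' cfg$library_sizes
simulation_config <- function(n_genes = 12000,
                              n_tissues = 6,
                              library_sizes = c(
                                embryo = 323897, liver = 392890,
                                muscle = 325646, skin = 252349,
                                spleen = 287902, testes = 299755
                              ),
                              profile_concentration = c(0.35, 2.5),
                              mixture_prop = c(0.6, 0.4),
                              mean_expression_dispersion = 1.0,
                              contigs_per_gene_mean = 1,
                              contaminant_fraction = 5e-4,
                              omega_coupling = 1,
                              abundance_tau_coupling = 0,
                              seed = 1L) {
  if (n_genes < 1 || n_tissues < 2) {
    abort("n_genes must be >= 1 and n_tissues >= 2")
  }
  if (length(library_sizes) != n_tissues) {
    abort("library_sizes must have length n_tissues")
  }
  if (any(library_sizes <= 0)) abort("library sizes must be positive")
  if (is.null(names(library_sizes))) {
    names(library_sizes) <- paste0("tissue", seq_len(n_tissues))
  }
  if (any(profile_concentration <= 0)) {
    abort("profile_concentration must be positive")
  }
  if (length(profile_concentration) > 1) {
    if (length(mixture_prop) != length(profile_concentration) ||
        abs(sum(mixture_prop) - 1) > 1e-8 || any(mixture_prop < 0)) {
      abort("mixture_prop must be non-negative weights summing to 1")
    }
  }
  if (mean_expression_dispersion <= 0) {
    abort("mean_expression_dispersion must be positive")
  }
  if (contigs_per_gene_mean < 0) abort("contigs_per_gene_mean must be >= 0")
  if (contaminant_fraction < 0 || contaminant_fraction >= 1) {
    abort("contaminant_fraction must be in [0, 1)")
  }
  if (abs(abundance_tau_coupling) > 1) {
    abort("abundance_tau_coupling must be in [-1, 1]")
  }
  structure(
    list(
      n_genes = as.integer(n_genes),
      n_tissues = as.integer(n_tissues),
      library_sizes = library_sizes,
      profile_concentration = profile_concentration,
      mixture_prop = mixture_prop,
      mean_expression_dispersion = mean_expression_dispersion,
      contigs_per_gene_mean = contigs_per_gene_mean,
      contaminant_fraction = contaminant_fraction,
      omega_coupling = omega_coupling,
      abundance_tau_coupling = abundance_tau_coupling,
      seed = as.integer(seed)
    ),
    class = "simulation_config"
  )
}

#' Generate the ground-truth gene catalog
#'
#' Draws, for each simulated gene: a transcript length, a log-normal relative
#' abundance, a Dirichlet tissue-proportion profile (optionally a two-component
#' mixture of a specific and a broad component), a simulated dN/dS omega
#' coupled to the true tissue specificity, and GO terms from a small synthetic
#' ontology in which some terms are enriched in high-tau (and some in low-tau)
#' genes by construction. True tau is computed from the expected TPM profile
#' with the same tau definition used for estimated expression (expected TPM
#' below the detection floor is floored, since sampling records such tissues
#' as zeros).
#'
#' @param config A [simulation_config()].
#' @return A `gene_catalog`: list with `truth` (per-gene tibble: `gene_id`,
#'   `length_bp`, `abundance`, `true_tau`, `omega`), `profiles` (long tibble:
#'   `gene_id`, `tissue`, `true_prop`, `true_tpm`), `annotation` (tibble
#'   mirroring a BioMart-style export: `gene_id`, `length_bp`, `omega`,
#'   `go_terms` semicolon-separated), and `planted_terms` (list of GO term ids
#'   enriched in high/low-tau genes by construction).
#' @export
generate_gene_catalog <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed_if(config$seed, {
    n <- config$n_genes
    k <- config$n_tissues
    tissues <- names(config$library_sizes)

    length_bp <- pmax(200L, as.integer(round(rlnorm(n, log(1500), 0.5))))
    abundance <- rlnorm(n, 0, config$mean_expression_dispersion)

    alpha <- config$profile_concentration
    if (length(alpha) == 1) {
      comp <- rep(1L, n)
    } else {
      comp <- sample(seq_along(alpha), n, replace = TRUE,
                     prob = config$mixture_prop)
    }
    prop <- matrix(0, n, k, dimnames = list(NULL, tissues))
    for (ci in unique(comp)) {
      idx <- which(comp == ci)
      prop[idx, ] <- rdirichlet(length(idx), alpha[ci], k = k)
    }

    # Optional rank coupling between log abundance and specificity: reorder
    # profiles (by their tau rank) against a Gaussian copula of log abundance.
    rho <- config$abundance_tau_coupling
    prop_tau <- compute_tau(prop * 1e6, floor_all = TRUE) # scale-free ranking
    if (rho != 0) {
      z_ab <- scale(log(abundance))[, 1]
      z <- rho * z_ab + sqrt(1 - rho^2) * rnorm(n)
      # genes with high z get the high-tau profiles
      ord <- order(prop_tau)[rank(z, ties.method = "first")]
      prop <- prop[ord, , drop = FALSE]
    }

    expected_tpm <- true_tpm_matrix(abundance, prop)
    true_tau <- compute_tau(expected_tpm, floor_all = TRUE)

    omega <- pmax(
      exp(log(0.15) + config$omega_coupling * true_tau + rnorm(n, 0, 0.7)) - 0.02,
      0
    )

    gene_id <- sprintf("GENE%05d", seq_len(n))
    go <- assign_go_terms(true_tau)

    truth <- tibble(
      gene_id = gene_id, length_bp = length_bp, abundance = abundance,
      true_tau = true_tau, omega = omega
    )
    profiles <- tibble(
      gene_id = rep(gene_id, each = k),
      tissue = rep(tissues, times = n),
      true_prop = as.vector(t(prop)),
      true_tpm = as.vector(t(expected_tpm))
    )
    annotation <- tibble(
      gene_id = gene_id, length_bp = length_bp, omega = omega,
      go_terms = go$terms
    )
    structure(
      list(truth = truth, profiles = profiles, annotation = annotation,
           planted_terms = go$planted, tissues = tissues),
      class = "gene_catalog"
    )
  })
}

# Expected TPM per gene x tissue: within each library, a gene's expected read
# share is abundance * tissue proportion, renormalised over genes.
true_tpm_matrix <- function(abundance, prop) {
  w <- prop * abundance
  sweep(w, 2, colSums(w), "/") * 1e6
}

# Synthetic flat ontology: 30 terms; 5 enriched in high-tau genes, 5 in
# low-tau genes, the rest neutral. Assignment probabilities depend on tau for
# planted terms only.
assign_go_terms <- function(true_tau) {
  n <- length(true_tau)
  terms <- sprintf("GO:S%04d", 1:30)
  planted_high <- terms[1:5]
  planted_low <- terms[6:10]
  neutral <- terms[11:30]
  member <- matrix(FALSE, n, 30, dimnames = list(NULL, terms))
  tau_sc <- (true_tau - min(true_tau)) / max(1e-9, diff(range(true_tau)))
  for (t in planted_high) member[, t] <- runif(n) < (0.02 + 0.30 * tau_sc)
  for (t in planted_low) member[, t] <- runif(n) < (0.02 + 0.30 * (1 - tau_sc))
  for (t in neutral) member[, t] <- runif(n) < 0.08
  term_str <- apply(member, 1, function(m) paste(terms[m], collapse = ";"))
  list(
    terms = term_str,
    planted = list(high_tau = planted_high, low_tau = planted_low)
  )
}

#' Simulate gene-level read counts per library
#'
#' Allocates each library's configured read total across genes by multinomial
#' sampling with probabilities proportional to `abundance x tissue proportion`.
#' Column sums equal the configured library sizes exactly.
#'
#' @param catalog A [generate_gene_catalog()] result.
#' @param config The matching [simulation_config()].
#' @param seed Optional seed overriding the config-derived default (which is
#'   `config$seed + 1`), e.g. for replicate draws.
#' @return Wide tibble: `gene_id` plus one integer count column per tissue.
#' @export
simulate_read_counts <- function(catalog, config, seed = NULL) {
  stopifnot(inherits(catalog, "gene_catalog"),
            inherits(config, "simulation_config"))
  tissues <- names(config$library_sizes)
  prop <- matrix(catalog$profiles$true_prop,
                 ncol = length(tissues), byrow = TRUE,
                 dimnames = list(catalog$truth$gene_id, tissues))
  if (nrow(prop) != config$n_genes) {
    abort("catalog and config disagree on the number of genes")
  }
  w <- prop * catalog$truth$abundance
  with_seed_if(seed %||% (config$seed + 1L), {
    counts <- vapply(
      seq_along(tissues),
      function(j) as.integer(rmultinom(1, config$library_sizes[j], w[, j])),
      integer(config$n_genes)
    )
  })
  counts <- matrix(as.integer(counts), ncol = length(tissues))
  colnames(counts) <- tissues
  bind_cols(tibble(gene_id = catalog$truth$gene_id), as_tibble(counts))
}

#' Fragment gene-level reads into contigs
#'
#' Splits each expressed gene's reads among one or more contigs (1 + a Poisson
#' number of extra fragments), with contig lengths given by random breakpoints
#' along the transcript and reads allocated to contigs proportionally to
#' contig length. Per-gene, per-tissue read totals are conserved exactly.
#' A configurable fraction of additional contaminant contigs is appended;
#' contaminants look ordinary in the count table (counts concentrated in one
#' random tissue) and are identified only through the truth map and the
#' synthetic alignment file, mirroring how foreign-organism contamination is
#' detected in practice.
#'
#' @param gene_counts Wide gene count tibble from [simulate_read_counts()].
#' @param catalog The matching [generate_gene_catalog()] result.
#' @param config The matching [simulation_config()].
#' @param seed Optional seed overriding `config$seed + 2`.
#' @return List with `contigs` (tibble: `contig_id`, `length`, per-tissue
#'   counts), `contig_map` (truth map `contig_id` -> `gene_id`, contaminants
#'   absent), and `contaminants` (tibble: `contig_id`, `subject_id` of the
#'   foreign reference each contaminant aligns to).
#' @export
fragment_into_contigs <- function(gene_counts, catalog, config, seed = NULL) {
  stopifnot(inherits(catalog, "gene_catalog"),
            inherits(config, "simulation_config"))
  tissues <- names(config$library_sizes)
  cnt <- as.matrix(gene_counts[tissues])
  if (any(cnt < 0)) abort("gene counts must be non-negative")
  gene_id <- gene_counts$gene_id
  len <- catalog$truth$length_bp[match(gene_id, catalog$truth$gene_id)]

  with_seed_if(seed %||% (config$seed + 2L), {
    expressed <- which(rowSums(cnt) > 0)
    n_frag <- 1L + rpois(length(expressed), config$contigs_per_gene_mean)

    pieces <- vector("list", length(expressed))
    for (i in seq_along(expressed)) {
      g <- expressed[i]
      nf <- n_frag[i]
      if (nf == 1L) {
        lens <- len[g]
      } else {
        br <- sort(runif(nf - 1L))
        lens <- pmax(1L, as.integer(round(diff(c(0, br, 1)) * len[g])))
      }
      split <- rmultinom_rows(cnt[g, ], matrix(rep(lens, each = length(tissues)),
                                               nrow = length(tissues)))
      # rows = tissues, cols = fragments after transpose handling:
      # rmultinom_rows draws per row; here each tissue's count is split
      # across fragments with prob ~ fragment length.
      pieces[[i]] <- list(gene = gene_id[g], lens = lens, counts = t(split))
    }

    contig_rows <- purrr::map_dfr(pieces, function(p) {
      tibble(
        gene_id = p$gene,
        length = p$lens,
        as_tibble(`colnames<-`(p$counts, tissues))
      )
    })
    contig_rows$contig_id <- sprintf("CTG%06d", seq_len(nrow(contig_rows)))

    # contaminant contigs: extra reads concentrated in one random tissue
    n_cont <- round(config$contaminant_fraction * nrow(contig_rows) /
                      max(1e-12, 1 - config$contaminant_fraction))
    contaminants <- tibble(contig_id = character(), subject_id = character())
    if (n_cont > 0) {
      main <- sample(length(tissues), n_cont, replace = TRUE)
      totals <- 4L + rpois(n_cont, 25)
      p <- matrix(0.1 / (length(tissues) - 1), n_cont, length(tissues))
      p[cbind(seq_len(n_cont), main)] <- 0.9
      ccounts <- rmultinom_rows(totals, p)
      colnames(ccounts) <- tissues
      cont_ids <- sprintf("CTG%06d", nrow(contig_rows) + seq_len(n_cont))
      cont_rows <- bind_cols(
        tibble(gene_id = NA_character_,
               length = pmax(60L, as.integer(round(rlnorm(n_cont, log(200), 0.4)))),
               contig_id = cont_ids),
        as_tibble(ccounts)
      )
      contig_rows <- bind_rows(contig_rows, cont_rows)
      contaminants <- tibble(
        contig_id = cont_ids,
        subject_id = sprintf("smed_scaffold_%03d", sample(1:20, n_cont, TRUE))
      )
    }
  })

  contigs <- contig_rows |>
    select("contig_id", "length", all_of(tissues))
  contig_map <- contig_rows |>
    filter(!is.na(.data$gene_id)) |>
    select("contig_id", "gene_id")
  list(contigs = contigs, contig_map = contig_map, contaminants = contaminants)
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper chaining [generate_gene_catalog()],
#' [simulate_read_counts()] and [fragment_into_contigs()], and synthesising a
#' tabular (BLAST outfmt-6 dialect) alignment file in memory: every
#' non-contaminant contig hits its true gene at e-value 1e-50, contaminant
#' contigs hit a foreign-organism scaffold, and a random subset of contigs
#' carries additional decoy hits whose e-values all exceed 1e-10.
#'
#' @inheritParams simulate_read_counts
#' @return A `dge_simulation` list: `config`, `catalog`, `gene_counts`,
#'   `contigs`, `contig_map`, `contaminants`, `alignments` (12-column tibble),
#'   `contaminant_subjects` (character vector of foreign subject ids).
#' @export
simulate_dge <- function(config) {
  catalog <- generate_gene_catalog(config)
  gene_counts <- simulate_read_counts(catalog, config)
  frag <- fragment_into_contigs(gene_counts, catalog, config)
  aln <- with_seed_if(config$seed + 3L,
                      synth_alignments(frag, catalog))
  structure(
    list(
      config = config, catalog = catalog, gene_counts = gene_counts,
      contigs = frag$contigs, contig_map = frag$contig_map,
      contaminants = frag$contaminants, alignments = aln,
      contaminant_subjects = unique(frag$contaminants$subject_id)
    ),
    class = "dge_simulation"
  )
}

# Build a 12-column outfmt-6-style hit table for a fragmentation result.
synth_alignments <- function(frag, catalog) {
  true_hits <- frag$contig_map |>
    left_join(frag$contigs |> select("contig_id", "length"), by = "contig_id") |>
    left_join(catalog$truth |> select("gene_id", "length_bp"), by = "gene_id")
  n <- nrow(true_hits)
  sstart <- pmax(1L, as.integer(round(runif(n) * pmax(1, true_hits$length_bp - true_hits$length))))
  hits <- tibble(
    qseqid = true_hits$contig_id,
    sseqid = true_hits$gene_id,
    pident = round(runif(n, 96, 100), 2),
    length = true_hits$length,
    mismatch = as.integer(round(true_hits$length * 0.01)),
    gapopen = 0L,
    qstart = 1L,
    qend = true_hits$length,
    sstart = sstart,
    send = pmin(true_hits$length_bp, sstart + true_hits$length - 1L),
    evalue = 1e-50,
    bitscore = round(1.8 * true_hits$length, 1)
  )
  cont <- frag$contaminants
  if (nrow(cont) > 0) {
    clen <- frag$contigs$length[match(cont$contig_id, frag$contigs$contig_id)]
    hits <- bind_rows(hits, tibble(
      qseqid = cont$contig_id, sseqid = cont$subject_id,
      pident = round(runif(nrow(cont), 97, 100), 2),
      length = clen, mismatch = 0L, gapopen = 0L,
      qstart = 1L, qend = clen, sstart = 1L, send = clen,
      evalue = 1e-40, bitscore = round(1.8 * clen, 1)
    ))
  }
  # decoy hits: always above the 1e-10 cutoff, to random genes
  n_decoy <- max(1L, round(0.3 * nrow(hits)))
  dq <- sample(hits$qseqid, n_decoy, replace = TRUE)
  dlen <- pmax(30L, as.integer(round(runif(n_decoy, 30, 80))))
  decoys <- tibble(
    qseqid = dq,
    sseqid = sample(catalog$truth$gene_id, n_decoy, replace = TRUE),
    pident = round(runif(n_decoy, 80, 95), 2),
    length = dlen, mismatch = as.integer(round(dlen * 0.1)), gapopen = 1L,
    qstart = 1L, qend = dlen, sstart = 10L, send = 10L + dlen - 1L,
    evalue = 10^runif(n_decoy, -9, -1),
    bitscore = round(0.9 * dlen, 1)
  )
  bind_rows(hits, decoys) |> arrange(.data$qseqid, .data$evalue)
}

#' Write a synthetic fixture bundle to disk
#'
#' Writes TSV count tables (contig- and gene-level), the annotation table, the
#' synthetic tabular alignment file (headerless, 12-column outfmt-6 dialect),
#' the contaminant subject list, library sizes, and the ground-truth tables.
#' Everything round-trips through [read_fixture_bundle()].
#'
#' @param sim A [simulate_dge()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "dge_simulation"))
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0) {
    abort(paste0("cannot write to directory: ", dir))
  }
  p <- function(f) file.path(dir, f)
  readr::write_tsv(sim$contigs, p("contig_counts.tsv"))
  readr::write_tsv(sim$gene_counts, p("gene_counts.tsv"))
  readr::write_tsv(sim$catalog$annotation, p("annotation.tsv"))
  readr::write_tsv(sim$alignments, p("alignments.tsv"), col_names = FALSE)
  readr::write_tsv(sim$catalog$truth, p("truth_genes.tsv"))
  readr::write_tsv(sim$catalog$profiles, p("truth_profiles.tsv"))
  readr::write_tsv(sim$contig_map, p("truth_contig_map.tsv"))
  readr::write_tsv(
    tibble(tissue = names(sim$config$library_sizes),
           reads = as.integer(sim$config$library_sizes)),
    p("library_sizes.tsv")
  )
  writeLines(sim$contaminant_subjects, p("contaminant_subjects.txt"))
  invisible(dir)
}

#' Read a fixture bundle written by [write_fixture_bundle()]
#'
#' @param dir Directory containing the bundle.
#' @return List with `contigs`, `gene_counts`, `annotation`, `alignments`
#'   (path, for [read_blast_tabular()]), `truth`, `profiles`, `contig_map`,
#'   `library_sizes`, `contaminant_subjects`.
#' @export
read_fixture_bundle <- function(dir) {
  p <- function(f) file.path(dir, f)
  for (f in c("contig_counts.tsv", "gene_counts.tsv", "annotation.tsv",
              "alignments.tsv", "library_sizes.tsv")) {
    if (!file.exists(p(f))) abort(paste0("missing fixture file: ", p(f)))
  }
  libs <- readr::read_tsv(p("library_sizes.tsv"), show_col_types = FALSE)
  list(
    contigs = readr::read_tsv(p("contig_counts.tsv"), show_col_types = FALSE),
    gene_counts = readr::read_tsv(p("gene_counts.tsv"), show_col_types = FALSE),
    annotation = readr::read_tsv(p("annotation.tsv"), show_col_types = FALSE) |>
      mutate(go_terms = tidyr::replace_na(as.character(.data$go_terms), "")),
    alignments = p("alignments.tsv"),
    truth = readr::read_tsv(p("truth_genes.tsv"), show_col_types = FALSE),
    profiles = readr::read_tsv(p("truth_profiles.tsv"), show_col_types = FALSE),
    contig_map = readr::read_tsv(p("truth_contig_map.tsv"), show_col_types = FALSE),
    library_sizes = setNames(libs$reads, libs$tissue),
    contaminant_subjects = readLines(p("contaminant_subjects.txt"))
  )
}
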