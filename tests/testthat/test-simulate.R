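test_that("config validation rejects impossible settings", {
  expect_error(small_config(n_genes = 0), "n_genes")
  expect_error(small_config(contaminant_fraction = 1), "contaminant_fraction")
  expect_error(small_config(mean_expression_dispersion = -1), "dispersion")
  expect_error(simulation_config(n_tissues = 3,
                                 library_sizes = c(a = 1, b = 2)),
               "length")
})

test_that("gene catalog is deterministic under a fixed seed", {
  a <- generate_gene_catalog(small_config(seed = 42))
  b <- generate_gene_catalog(small_config(seed = 42))
  expect_identical(a$truth, b$truth)
  expect_identical(a$profiles, b$profiles)
  expect_identical(a$annotation, b$annotation)
  c <- generate_gene_catalog(small_config(seed = 43))
  expect_false(identical(a$truth, c$truth))
})

test_that("Dirichlet concentration limits pin the true tau range", {
  # near-uniform profiles: tau close to 0 for every gene
  flat <- generate_gene_catalog(small_config(
    n_genes = 100, profile_concentration = 5000, mixture_prop = NULL, seed = 1
  ))
  expect_lt(max(flat$truth$true_tau), 0.05)
  # near one-hot profiles: tau at the single-tissue maximum, which for a
  # floored profile is the closed form 1 - 1/log2(TPM_max)
  hot <- generate_gene_catalog(small_config(
    n_genes = 100, profile_concentration = 0.001, mixture_prop = NULL, seed = 1
  ))
  tpm <- matrix(hot$profiles$true_tpm, ncol = 6, byrow = TRUE)
  one_hot <- rowSums(tpm > 2) == 1
  expect_gt(mean(one_hot), 0.9)
  expect_equal(hot$truth$true_tau[one_hot],
               1 - 1 / log2(apply(tpm[one_hot, ], 1, max)))
  # proportions always sum to 1, tau always within [0, 1]
  sums <- hot$profiles |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(s = sum(true_prop))
  expect_true(all(abs(sums$s - 1) < 1e-8))
  expect_true(all(hot$truth$true_tau >= 0 & hot$truth$true_tau <= 1))
})

test_that("true tau equals compute_tau applied to noise-free expected TPM", {
  cat <- generate_gene_catalog(small_config(n_genes = 200, seed = 3))
  tpm <- matrix(cat$profiles$true_tpm, ncol = 6, byrow = TRUE)
  expect_equal(cat$truth$true_tau, compute_tau(tpm, floor_all = TRUE))
})

test_that("simulated omega is positively rank-coupled to true tau", {
  cat <- generate_gene_catalog(simulation_config(
    n_genes = 2000, library_sizes = deep_library_sizes(3e5),
    omega_coupling = 1, seed = 11
  ))
  sub <- withr::with_seed(1, sample.int(2000, 1000))
  r <- cor(cat$truth$true_tau[sub], log(cat$truth$omega[sub] + 1),
           method = "spearman")
  expect_gt(r, 0.1)
  # negative coupling flips the sign
  cat2 <- generate_gene_catalog(simulation_config(
    n_genes = 2000, library_sizes = deep_library_sizes(3e5),
    omega_coupling = -1, seed = 11
  ))
  expect_lt(cor(cat2$truth$true_tau, cat2$truth$omega, method = "spearman"), 0)
})

test_that("abundance_tau_coupling plants a rank correlation with abundance", {
  cat <- generate_gene_catalog(small_config(
    n_genes = 2000, abundance_tau_coupling = -0.5, seed = 5
  ))
  r <- cor(log(cat$truth$abundance), cat$truth$true_tau, method = "spearman")
  expect_lt(r, -0.25)
})

test_that("read counts conserve library sizes exactly", {
  cfg <- small_config(seed = 2)
  cat <- generate_gene_catalog(cfg)
  counts <- simulate_read_counts(cat, cfg)
  expect_identical(unname(colSums(as.matrix(counts[-1]))),
                   unname(as.double(cfg$library_sizes)))
  expect_identical(sum(as.matrix(counts[-1])), as.integer(sum(cfg$library_sizes)))
})

test_that("a single gene receives all reads in every library", {
  cfg <- small_config(n_genes = 1, seed = 9)
  cat <- generate_gene_catalog(cfg)
  counts <- simulate_read_counts(cat, cfg)
  expect_identical(unname(unlist(counts[1, -1])),
                   unname(as.integer(cfg$library_sizes)))
})

test_that("empirical multinomial means match expectation", {
  # tiny catalog; 1000 replicate draws; compare each gene x tissue mean count
  # to library_size * p within 3 standard errors of the Monte-Carlo mean
  cfg <- small_config(n_genes = 5, depth = 2000, seed = 4)
  cat <- generate_gene_catalog(cfg)
  prop <- matrix(cat$profiles$true_prop, ncol = 6, byrow = TRUE)
  w <- prop * cat$truth$abundance
  p <- sweep(w, 2, colSums(w), "/")
  reps <- vapply(seq_len(1000), function(i) {
    as.matrix(simulate_read_counts(cat, cfg, seed = 1000 + i)[-1]) + 0
  }, matrix(0, 5, 6))
  emp_mean <- apply(reps, c(1, 2), mean)
  emp_se <- apply(reps, c(1, 2), sd) / sqrt(1000)
  expected <- 2000 * p
  expect_true(all(abs(emp_mean - expected) <= 3 * emp_se + 1e-9))
})

test_that("fragmentation conserves per-gene, per-tissue reads", {
  cfg <- small_config(n_genes = 100, contigs_per_gene_mean = 2,
                      contaminant_fraction = 0, seed = 6)
  cat <- generate_gene_catalog(cfg)
  counts <- simulate_read_counts(cat, cfg)
  frag <- fragment_into_contigs(counts, cat, cfg)
  regrouped <- frag$contigs |>
    dplyr::inner_join(frag$contig_map, by = "contig_id") |>
    dplyr::group_by(gene_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(six_tissues), sum))
  merged <- dplyr::inner_join(counts, regrouped, by = "gene_id",
                              suffix = c("", ".frag"))
  for (t in six_tissues) {
    expect_identical(merged[[t]], as.integer(merged[[paste0(t, ".frag")]]))
  }
  # contig lengths never exceed the transcript length
  lens <- frag$contigs |>
    dplyr::inner_join(frag$contig_map, by = "contig_id") |>
    dplyr::inner_join(cat$truth, by = "gene_id")
  expect_true(all(lens$length <= lens$length_bp))
})

test_that("zero fragmentation mean gives exactly one contig per expressed gene", {
  cfg <- small_config(n_genes = 80, contigs_per_gene_mean = 1e-12,
                      contaminant_fraction = 0, seed = 8)
  cat <- generate_gene_catalog(cfg)
  counts <- simulate_read_counts(cat, cfg)
  frag <- fragment_into_contigs(counts, cat, cfg)
  expressed <- counts$gene_id[rowSums(as.matrix(counts[-1])) > 0]
  expect_identical(sort(frag$contig_map$gene_id), sort(expressed))
})

test_that("contaminant contigs are absent from the truth map", {
  cfg <- small_config(n_genes = 200, contaminant_fraction = 0.02, seed = 10)
  sim <- simulate_dge(cfg)
  expect_gt(nrow(sim$contaminants), 0)
  expect_length(intersect(sim$contaminants$contig_id,
                          sim$contig_map$contig_id), 0)
  # but they look ordinary in the count table
  expect_true(all(sim$contaminants$contig_id %in% sim$contigs$contig_id))
})

test_that("fixture bundle round-trips and decoys exceed the cutoff", {
  cfg <- small_config(n_genes = 120, contaminant_fraction = 0.02, seed = 12)
  sim <- simulate_dge(cfg)
  dir <- tempfile("bundle_")
  write_fixture_bundle(sim, dir)
  back <- read_fixture_bundle(dir)
  expect_equal(as.data.frame(back$contigs), as.data.frame(sim$contigs))
  expect_equal(as.data.frame(back$gene_counts), as.data.frame(sim$gene_counts))
  expect_equal(back$library_sizes, cfg$library_sizes)
  expect_equal(as.data.frame(back$annotation),
               as.data.frame(sim$catalog$annotation))
  # decoy hits (anything not a true or contaminant best hit) all above 1e-10
  decoys <- sim$alignments$evalue[sim$alignments$evalue > 1e-30]
  expect_gt(length(decoys), 0)
  expect_true(all(decoys > 1e-10))
  # alignment file parses with the tabular reader
  hits <- read_blast_tabular(back$alignments)
  expect_true(all(hits$evalue <= 1e-10))
  expect_setequal(unique(hits$qseqid), sim$contigs$contig_id)
})

test_that("vectorised multinomial sampler matches rmultinom in distribution", {
  p <- c(0.5, 0.3, 0.2)
  a <- withr::with_seed(1, taudge:::rmultinom_rows(rep(1000L, 2000),
                                                   matrix(p, 2000, 3,
                                                          byrow = TRUE)))
  b <- withr::with_seed(2, t(stats::rmultinom(2000, 1000, p)))
  expect_identical(rowSums(a), rep(1000, 2000))
  # compare first and second moments
  expect_equal(colMeans(a), colMeans(b), tolerance = 0.01)
  expect_equal(apply(a, 2, var), apply(b, 2, var), tolerance = 0.15)
})
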