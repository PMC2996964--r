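# Exhaustive enumeration oracle for the overrepresentation p-value: over all
# size-k subsets of a small universe, the probability of drawing at least
# `obs` genes annotated with the term.
enum_overrep_p <- function(universe_size, term_count, set_size, obs) {
  idx <- utils::combn(universe_size, set_size)
  annotated <- seq_len(term_count) # wlog the first term_count genes
  hits <- apply(idx, 2, function(s) sum(s %in% annotated))
  mean(hits >= obs)
}

test_that("hypergeometric p matches exhaustive enumeration on small universes", {
  # worked case: universe 10, term annotates 4, set of 5 contains all 4
  genes <- sprintf("g%02d", 1:10)
  ann <- tibble::tibble(
    gene_id = genes,
    go_terms = c(rep("GO:X", 4), rep("", 6))
  )
  res <- go_overrepresentation(genes[c(1:4, 10)], genes, ann)
  expect_equal(res$p_raw[res$term_id == "GO:X"], 6 / 252)
  expect_equal(res$set_count[res$term_id == "GO:X"], 4L)
  # randomised small cases against the enumeration oracle
  cases <- withr::with_seed(17, lapply(1:12, function(i) {
    list(u = sample(5:12, 1), m = sample(1:4, 1), k = sample(2:4, 1))
  }))
  for (cs in cases) {
    u <- sprintf("u%02d", seq_len(cs$u))
    ann <- tibble::tibble(
      gene_id = u,
      go_terms = c(rep("GO:T", cs$m), rep("", cs$u - cs$m))
    )
    set <- withr::with_seed(cs$u * cs$m + cs$k, sample(u, cs$k))
    obs <- sum(set %in% u[seq_len(cs$m)])
    got <- go_overrepresentation(set, u, ann)
    p <- got$p_raw[got$term_id == "GO:T"]
    if (length(p) == 0) p <- 1 # term absent when no universe gene carries it
    expect_equal(p, enum_overrep_p(cs$u, cs$m, cs$k, obs), tolerance = 1e-12)
  }
})

test_that("degenerate enrichment cases behave sensibly", {
  genes <- sprintf("g%d", 1:8)
  ann <- tibble::tibble(gene_id = genes,
                        go_terms = rep(c("GO:A", "GO:B"), 4))
  # set == universe: no enrichment possible, every p = 1
  all_in <- go_overrepresentation(genes, genes, ann)
  expect_true(all(all_in$p_raw == 1))
  # set must be a subset of the universe
  expect_error(go_overrepresentation(c("nope"), genes, ann), "subset")
  # a term with zero set count can never be overrepresented: P[X >= 0] = 1
  one <- go_overrepresentation(genes[2], genes, ann)
  expect_equal(one$p_raw[one$term_id == "GO:A"], 1)
})

test_that("BH adjustment is monotone and never below the raw p", {
  genes <- sprintf("g%03d", 1:60)
  terms <- sprintf("GO:%02d", 1:12)
  ann <- withr::with_seed(19, tibble::tibble(
    gene_id = genes,
    go_terms = vapply(genes, function(g) {
      paste(sample(terms, sample(1:5, 1)), collapse = ";")
    }, "")
  ))
  set <- withr::with_seed(20, sample(genes, 15))
  res <- go_overrepresentation(set, genes, ann)
  expect_true(all(res$p_adjusted >= res$p_raw))
  ord <- order(res$p_raw)
  expect_true(all(diff(res$p_adjusted[ord]) >= -1e-12))
  bonf <- go_overrepresentation(set, genes, ann, adjust = "bonferroni")
  expect_true(all(bonf$p_adjusted >= res$p_adjusted - 1e-12))
})

test_that("tau-extreme sets are deterministic, disjoint and boundary-tied by id", {
  tt <- tibble::tibble(
    entity_id = c("A", "B", "C"),
    tau = c(0.9, 0.1, 0.5),
    total_reads = 10L, max_tissue = "x", max_tie = FALSE, n_tissues = 6L
  )
  s <- select_tau_extreme_sets(tt, k = 1)
  expect_equal(s$high_tau, "A")
  expect_equal(s$low_tau, "B")
  # all tau equal: boundary resolved lexicographically, sets disjoint
  tie <- tibble::tibble(entity_id = c("d", "c", "b", "a"), tau = 0.5)
  s2 <- select_tau_extreme_sets(tie, k = 2)
  expect_equal(s2$high_tau, c("a", "b"))
  expect_equal(s2$low_tau, c("a", "b")) # same order statistics, same rule
  # k equal to half the genes partitions distinct taus
  part <- tibble::tibble(entity_id = letters[1:6], tau = (1:6) / 10)
  s3 <- select_tau_extreme_sets(part, k = 3)
  expect_setequal(c(s3$high_tau, s3$low_tau), letters[1:6])
  expect_error(select_tau_extreme_sets(part, k = 4), "at least 8")
})

test_that("terms planted in high-tau genes outrank neutral terms", {
  reps <- 50
  top_is_planted <- logical(reps)
  for (i in seq_len(reps)) {
    cat <- generate_gene_catalog(small_config(n_genes = 500, seed = 100 + i))
    tt <- tibble::tibble(entity_id = cat$truth$gene_id,
                         tau = cat$truth$true_tau)
    sets <- select_tau_extreme_sets(tt, k = 100)
    res <- go_overrepresentation(sets$high_tau, cat$truth$gene_id,
                                 cat$annotation)
    planted <- cat$planted_terms$high_tau
    mean_rank_planted <- mean(match(planted, res$term_id))
    mean_rank_other <- mean(match(setdiff(res$term_id, c(planted, cat$planted_terms$low_tau)),
                                  res$term_id))
    top_is_planted[i] <- mean_rank_planted < mean_rank_other
  }
  expect_gte(mean(top_is_planted), 0.95)
})

test_that("correlate reproduces closed-form coefficients", {
  d <- data.frame(x = 1:3, y = c(2, 4, 6), z = c(10, 1, 5))
  expect_equal(correlate(d, "x", "y")$estimate, 1)
  rs <- correlate(d, "x", "z", method = "spearman")
  expect_equal(rs$estimate, -0.5) # 1 - 6*sum(d^2)/(n(n^2-1)), d^2 = (4,1,1)
  expect_equal(rs$df, 1L)
  expect_error(correlate(d, "x", "y", transform_y = "log10") -> ._, NA)
  expect_error(correlate(data.frame(x = 1:3, y = rep(2, 3)), "x", "y"),
               "zero variance")
  expect_error(correlate(d[1:2, ], "x", "y"), "at least 3")
})

test_that("spearman is invariant to strictly monotone transforms", {
  d <- withr::with_seed(23, data.frame(x = rexp(50), y = rexp(50)))
  base <- correlate(d, "x", "y", method = "spearman")$estimate
  expect_equal(correlate(dplyr::mutate(d, x = log(x)), "x", "y",
                         method = "spearman")$estimate, base)
  expect_equal(correlate(dplyr::mutate(d, y = y^3), "x", "y",
                         method = "spearman")$estimate, base)
  # matching the omega transform used in plots: log(omega + 1)
  expect_equal(correlate(dplyr::mutate(d, y = log1p(y)), "x", "y",
                         method = "spearman")$estimate, base)
})

test_that("group comparisons reproduce hand-computed statistics", {
  d <- data.frame(v = c(1, 2, 3, 4, 5, 6), g = rep(c("a", "b"), each = 3))
  kw <- group_compare(d, "v", "g", method = "kruskal")
  expect_equal(kw$statistic, 3.857143, tolerance = 1e-6)
  expect_equal(kw$df, 1)
  # identical groups: statistic ~ 0
  same <- data.frame(v = rep(c(1, 2, 3), 2), g = rep(c("a", "b"), each = 3))
  expect_equal(group_compare(same, "v", "g", method = "anova")$statistic, 0)
  # six groups give df = 5
  six <- withr::with_seed(29, data.frame(v = rnorm(60),
                                         g = rep(six_tissues, each = 10)))
  expect_equal(group_compare(six, "v", "g", method = "kruskal")$df, 5)
  aov6 <- group_compare(six, "v", "g", method = "anova")
  expect_equal(aov6$df, 5)
  expect_equal(aov6$df_resid, 54)
  expect_error(group_compare(d[1:3, ], "v", "g"), "2 groups")
})

test_that("per-tissue summary: counts, CIs and degenerate cases", {
  tt <- tibble::tibble(
    entity_id = sprintf("g%02d", 1:12),
    tau = rep(c(0.2, 0.8), 6),
    total_reads = 10L,
    max_tissue = rep(c("liver", "spleen"), each = 6),
    max_tie = FALSE, n_tissues = 6L
  )
  ann <- tibble::tibble(gene_id = tt$entity_id,
                        omega = rep(c(0.1, 0.4), each = 6))
  s <- summarize_by_max_tissue(tt, ann, n_boot = 500, seed = 1)
  expect_equal(s$n_max, c(6L, 6L))
  expect_equal(s$mean_omega, c(0.1, 0.4))
  # equal omega within a tissue: CI width 0
  expect_equal(s$omega_ci_lo, s$omega_ci_hi)
  # n < 3 gives NA CIs
  one <- summarize_by_max_tissue(tt[c(1, 7), ], ann, n_boot = 100)
  expect_true(all(is.na(one$omega_ci_lo)))
  # exclusive-expression counts from the count table
  counts <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    liver = c(5L, 3L, 0L), spleen = c(0L, 2L, 9L)
  )
  tt2 <- tibble::tibble(entity_id = counts$gene_id, tau = 0.5,
                        total_reads = c(5L, 5L, 9L),
                        max_tissue = c("liver", "liver", "spleen"),
                        max_tie = FALSE, n_tissues = 2L)
  s2 <- summarize_by_max_tissue(tt2, ann[1:3, ], counts = counts,
                                n_boot = 100, seed = 2)
  expect_equal(s2$n_exclusive[s2$tissue == "liver"], 1L)
  expect_equal(s2$n_exclusive[s2$tissue == "spleen"], 1L)
})

test_that("tissue with the lowest planted omega has the lowest summary mean", {
  cfg <- small_config(n_genes = 800, seed = 41, omega_coupling = 2)
  cat <- generate_gene_catalog(cfg)
  counts <- simulate_read_counts(cat, cfg)
  tt <- tau_table(counts, cfg$library_sizes)
  # plant: embryo-max genes get the smallest omega by construction
  ann <- cat$annotation
  embryo_max <- tt$entity_id[!is.na(tt$max_tissue) & tt$max_tissue == "embryo"]
  ann$omega[ann$gene_id %in% embryo_max] <- ann$omega[ann$gene_id %in% embryo_max] / 10
  s <- summarize_by_max_tissue(tt, ann, n_boot = 500, seed = 3)
  expect_equal(s$tissue[which.min(s$mean_omega)], "embryo")
})
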