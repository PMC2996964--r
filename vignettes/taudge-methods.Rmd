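---
title: "Methods: tissue specificity, sampling bias, and enrichment in digital gene expression data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tissue specificity, sampling bias, and enrichment in digital gene expression data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taudge)
```

`taudge` analyses digital gene expression data: read counts per contig per
tissue library, as produced by 454/EST sequencing of cDNA from several
tissues. This vignette is the package's account of the methods — the models,
their assumptions, the tunable parameters, and the design choices made where
the method descriptions in the literature are ambiguous.

## Count-proportion TPM

Expression is normalised as `TPM = reads / library_size × 1e6`, a read-count
proportion. This is the transcripts-per-million of the EST literature, **not**
the length-normalised TPM of modern RNA-seq: with single-pass reads and
partial transcript coverage, a per-transcript length correction is neither
possible nor intended, and the published tables this package reproduces use
the proportion definition. `compute_tpm()` and `infer_counts_from_tpm()` are
exact inverses up to the half-read rounding of the back-inference.

## The τ index and its conventions

For a profile of TPM values over `N ≥ 2` tissues,

\[
\tau = \frac{\sum_{i=1}^{N} (1 - x_i / x_{max})}{N - 1}, \qquad
x_i = \log_2(\mathrm{TPM}_i),
\]

with three conventions that matter in sparse count data:

* **Zero floor.** Tissues with no detected expression enter at a floor of
  2 TPM (`floor_tpm = 2`). The floor applies to exact zeros only; small
  positive TPM values enter unfloored. The log base is not dictated by the τ
  formula itself; log2 together with the floor of 2 is pinned in the test
  suite by exact reproduction of six published τ values (0.336, 0.497, 0.519,
  0.602, 0.817, 0.833) from their printed TPM profiles.
* **Read filter.** Entities with 3 or fewer reads in total are reported as
  filtered (`-`): τ from a handful of reads is dominated by sampling noise.
  "Fewer than four" and "three or fewer" are one rule, `total_reads >= 4`.
* **N is the number of libraries supplied.** τ values are comparable only at
  fixed N; `tau_table()` records `n_tissues` in every result. The MHC table
  uses seven libraries (six 454 tissues plus a brain EST library); genome-wide
  analyses in the motivating study used six.

When a published table prints TPM to one decimal, τ recomputed from the
printed values can differ in the third decimal from τ computed from the
underlying counts (near-single-tissue profiles are the sensitive case).
`tau_from_tpm_table()` therefore back-infers integer counts, recomputes exact
TPM, and computes τ from those — the path that reproduces all published
values exactly.

Two analytical properties of τ deserve emphasis:

* τ ∈ [0, 1] whenever all floored TPM values are ≥ 1. TPM strictly between 0
  and 1 (impossible for integer counts at library sizes up to 10⁶) would give
  negative logs; `compute_tau()` clamps such values to 1 with a warning.
* **τ is scale-dependent.** Multiplying a profile by a constant c shifts every
  `x_i` by `log2(c)`; the numerator terms `x_max − x_i` are unchanged but the
  denominator `x_max` grows, so τ shrinks roughly in proportion to
  `1/log2(scale)`. A gene's τ therefore declines slightly with its total
  expression even in noise-free data. This deterministic trend is part of what
  the resampling null (below) measures, alongside the sparsity-driven bias.

## The level-stratified resampling null

In shallow data, τ is mechanically inflated at low totals: a multinomial
sample of 5 reads from a broad profile usually lands in one or two tissues.
The observed negative correlation between `log10(total reads)` and τ
therefore mixes this sampling artefact with any biological coupling. The null
works as follows (`simulate_correlation_distribution()`):

1. Pool the tissue read-proportion vectors of all retained contigs
   (templates).
2. Build simulated datasets with exactly the observed number of contigs at
   each distinct total-read level; each simulated contig keeps a randomly
   drawn template's relative expression levels between tissues but has its
   integer counts redrawn from a multinomial at its level. Low totals thus
   genuinely produce sparse profiles — the mechanism being tested — while any
   abundance–specificity coupling is broken.
3. Compute the Pearson correlation between `log10(total)` and τ per simulated
   dataset (one dataset per distinct level by default, overridable via
   `n_sim`), and compare the observed coefficient against the simulated ones.

The multinomial is a modelling choice: the count-sampling law of the original
procedure is unstated, and the multinomial is the minimal distribution that
conserves a contig's total while respecting its tissue proportions. The two
published readings of the iteration count — one simulated dataset per level
versus the observed number of points per level — coincide under this design,
because a dataset matching the observed level composition *is* one with
`n_L` points at each level; both `mode` names are accepted and run the same
scheme.

**Comparison statistics.** `method = "t"` is the classical one-sample t-test
of the simulated coefficients against the observed one (`df = n_sim − 1`),
matching the published analysis. Note that it treats the observed coefficient
as a fixed constant; when the observed data are themselves a draw from the
null, the statistic is inflated by roughly `sqrt(n_sim)` and the test is
anticonservative. `method = "z"` is a calibrated prediction-interval variant,
`(mean_sim − observed) / (sd_sim · sqrt(1 + 1/n_sim))` against a
`t(n_sim − 1)` reference, with exact type-I error under normality (verified
by a 200-repetition calibration test in the suite). Use `"t"` to mirror the
published computation and `"z"` for a calibrated significance statement.

**Behaviour at depth.** With totals in the thousands the sparsity bias
vanishes, but the deterministic scale dependence of τ does not: over a wide
level range the null's mean correlation stays slightly negative at any depth.
The deep-coverage tests therefore use a narrow level band (totals
100,000–102,000), where the scale trend is negligible and the null mean is
statistically indistinguishable from zero — isolating exactly the component
that depth removes.

## Enrichment and group statistics

GO overrepresentation is a one-sided hypergeometric test per term
(`P[X ≥ set_count]`, the overrepresentation tail of Fisher's exact test),
with Benjamini–Hochberg adjustment across terms by default (Bonferroni via a
flag). The adjustment method behind the published "adjusted Fisher's p" is
unspecified; BH is the standard choice for GO scans. Terms are flat labels —
no ontology-graph propagation — matching how term lists were consumed by the
web tools of the period. The enrichment universe defaults to the detected
genes (the published wording "compared against all other … genes" suggests
the detected set); any universe can be supplied.

Correlations use `cor.test` (Spearman with average ranks for ties; `df = n −
2` reported alongside, as in the published results). Spearman statistics are
invariant to strictly monotone transforms, so the `log(ω + 1)` transform used
for plots does not affect them — asserted in the tests. Group comparisons are
tie-corrected Kruskal–Wallis or one-way ANOVA.

The per-tissue summary (`summarize_by_max_tissue()`) reports mean ω and mean
τ for genes with maximal expression in each tissue, with 95% confidence
intervals from a percentile bootstrap (10,000 resamples by default): ω is
heavily right-skewed, so a nonparametric interval is the defensible default;
a t-interval is available as a flag. CIs are `NA` below n = 3.

## The synthetic-data generator

`simulation_config()` + `simulate_dge()` emulate the statistical structure of
a multi-tissue 454 study, with full ground truth:

* **Tissue profiles** are Dirichlet. The default is a two-component mixture
  (α = 0.35 with weight 0.6; α = 2.5 with weight 0.4), giving a bimodal
  specificity distribution spanning housekeeping-like (τ ≈ 0.15) to
  single-tissue (τ > 0.8) profiles, as reported for real data.
* **Abundances** are log-normal with `sdlog = 1.0` by default. This is a
  calibration choice, not a literature fact: it reproduces the reported
  *maximum* contig depth (~6,000 reads) at the default scale of 12,000 genes
  and the six published library sizes (0.25–0.4 M reads each). The reported
  *median* of 6 reads per contig is dominated by tens of thousands of
  unannotated contigs and singletons that the generator deliberately does not
  simulate, so it is not a calibration target. The modest dispersion is also
  consistent with the DSN-normalised cDNA libraries of such studies, which
  flatten abundance ranges.
* **Counts** are multinomial per library, so column sums equal the configured
  library sizes exactly.
* **Fragmentation**: each expressed gene yields `1 + Poisson(λ)` contigs with
  lengths from random breakpoints along the transcript; reads are split
  across contigs proportionally to length (which induces the positive
  length–depth correlation seen in real assemblies). Per-gene, per-tissue
  totals are conserved exactly.
* **True τ** is computed from the expected TPM profile with the same τ
  definition as the estimator, except that all expected values below the
  floor are floored (`floor_all = TRUE`): expected-value profiles are
  continuous, sub-floor expectations are the tissues sampling records as
  zeros, and this keeps true τ within [0, 1].
* **ω** is simulated as `exp(log(0.15) + b·τ + N(0, 0.7)) − 0.02`, clipped at
  zero, with `b = omega_coupling` (default 1), planting a positive τ–ω rank
  correlation of roughly the magnitude reported for real data (~0.2).
* **`abundance_tau_coupling`** (default 0) plants a rank correlation between
  log abundance and true τ via a Gaussian copula reordering of the profiles —
  the biological coupling that the resampling null is designed to detect on
  top of the sampling bias.
* **Contaminants** (default fraction 5 × 10⁻⁴, the order observed in real
  assemblies) look ordinary in the count table; they are identifiable only
  through the synthetic alignment file, whose contaminant contigs hit a
  foreign-organism scaffold — so contaminant removal must run through the
  mapping module, as in a real analysis. Decoy alignments all carry e-values
  above the 1e-10 cutoff, so mapping accuracy on synthetic data is 100% by
  construction; this validates the plumbing, not the aligner.

What the generator does **not** emulate: actual sequence (no bases, no
flowgrams), cDNA normalisation chemistry (its flattening is absorbed into the
dispersion default), assembly errors and chimeric contigs, unannotated
transcription, and the distinct protocol of an EST library. Passing tests on
synthetic data therefore demonstrate the correctness of the statistical
machinery under the stated generative model — not robustness to assembly or
annotation artefacts in real data.

## Numerical and interface choices

* E-value cutoff is inclusive (`evalue ≤ 1e-10`), the BLAST community norm
  for an unstated direction; best-hit ties beyond (min e-value, max length)
  break lexicographically by subject id for determinism.
* Gene coverage is `100 × Σ contig lengths / gene length`, capped at 100 when
  overlapping contigs push the sum past the gene (the published description
  inverts numerator and denominator as printed, which would exceed 1 for low
  coverage and contradict the reported ~38% average; the capped ratio is the
  reading consistent with those numbers).
* Splice gaps use a strict `> 15` base rule on 1-based inclusive reference
  coordinates; overlapping segments are reported, never silently merged; BED
  export converts to 0-based half-open.
* Counts are integers; TPM-derived counts round half-up.
* Maximal-expression ties break by the fixed tissue order of the input table
  and are flagged.
* The bimodality coefficient in `tau_distribution_summary()` is Sarle's
  `(g1² + 1) / (g2 + 3(n−1)²/((n−2)(n−3)))`; values above 5/9 indicate
  flatter-than-uniform or bimodal shapes.
* All randomness is seeded through configuration or function arguments
  (`withr::with_seed`), never global state; re-running any pipeline with the
  same seed reproduces every statistical output byte for byte. The total-read
  correlation uses `log10`, but Pearson r is affine-invariant so the base is
  immaterial (asserted in tests).
* `run_pipeline()` writes a manifest (package version, seed, thresholds,
  input checksums, per-stage counts) so any number in any report is
  reproducible from config plus seed.

## Problem sizes used in the test suite

The suite favours the smallest sizes at which each property is decisive:
parameter recovery uses 2,000 genes at six libraries of 10⁶ reads (mean
absolute τ error ≈ 0.011, against a 0.02 bound); the power test for a planted
abundance–specificity coupling of −0.3 uses 20 repetitions of 5,000 contigs
with 30 simulated null datasets each; the type-I calibration uses 200
repetitions of 150 contigs; end-to-end pipeline tests run 250-gene synthetic
studies. A full synthetic run at 2,000 genes and six libraries completes in
seconds on one CPU.

## Known limitations

* τ comparisons across datasets with different N, different library sizes, or
  different depth regimes are confounded by the floor and by τ's scale
  dependence; the package records N and totals but cannot remove the
  confound.
* The count-proportion TPM ignores transcript length, so between-gene
  comparisons within a library are length-biased exactly as in the original
  EST methodology.
* The one-sample t comparison of observed versus simulated correlations is
  anticonservative by construction (see above); the calibrated variant is
  provided, but published-style results use the classical form.
* GO enrichment treats terms as independent flat labels; ancestor-term
  structure and term–term correlation are ignored.
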