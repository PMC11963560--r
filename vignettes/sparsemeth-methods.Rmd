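---
title: "Methods: models, parameters and design choices in sparsemeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in sparsemeth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsemeth)
```

# Scope

sparsemeth implements the downstream half of a sparse-methylome bisulfite
study: everything from per-cytosine CGmap call tables to QC, positional
profiles, and age-association statistics. Alignment, duplicate marking and
methylation calling are upstream of the package and out of scope; the CIGAR
match filter is included because it operates on the caller's SAM text and
belongs to the filtering chain.

# The observation model

Every statistic in the package treats a cytosine record as a binomial
observation. A site with true methylation level $p \in [0,1]$ sequenced at
coverage $c$ yields a methylated count

$$X \sim \mathrm{Binomial}\!\left(c,\ \min(p + \varepsilon, 1)\right),
\qquad \hat{m} = X / c,$$

where $\varepsilon$ is the bisulfite **non-conversion rate**: the fraction
of unmethylated cytosines that escape conversion and read as methylated.
Two consequences drive the QC design:

* on a genuinely unmethylated sequence ($p = 0$), $\hat m$ estimates
  $\varepsilon$ — hence `nonconversion_estimate()` summarizes levels on a
  control contig (mitochondrial DNA, which is unmethylated in most animals);
* true CpG methylation is **strand-symmetric**: the two cytosines of a CpG
  dyad (positions $i$ and $i+1$ on opposite strands) share one underlying
  $p$, so their observed levels differ only by binomial noise. Conversion
  artifacts have no reason to be symmetric. `strand_symmetry()` counts, among
  dyads with non-zero methylation on both strands, those with
  $|\hat m^+ - \hat m^-| < 0.05$ (strict inequality; both members must pass
  the coverage gate, default 10 reads, mirroring the global site filter —
  the threshold is a parameter because the underlying convention is not
  universal).

"Non-zero on both strands" means at least one methylated read on each
strand (level $> 0$ exactly); no epsilon is applied at that step.

# Filtering chain

Conventions used throughout, inclusive at every boundary:

| Step | Rule | Default |
|---|---|---|
| site filter | coverage $\ge$ `min_coverage` | 10 reads |
| alignment filter | summed CIGAR M lengths $\ge$ `min_matches` | 50 bases |
| matrix entry | covered in $\ge \lceil f \cdot n \rceil$ samples | $f = 0.8$ |
| gene filter | gene mean $\ge$ 10% in $\ge \lceil 0.8 n \rceil$ samples | as stated |
| variability filter | top $\lceil f \cdot n_\text{sites}\rceil$ by variance | $f = 0.2$ |

The sample-fraction rule uses ceiling rounding (0.8 of 17 samples means at
least 14); this is the conservative reading where the convention is not
fixed by the tool lineage. Variability is the across-sample variance (not
MAD), with ties broken by variance descending then genomic coordinate
ascending so the filter is deterministic.

Missing matrix cells are imputed by **correlated-sample kNN**: the missing
cell takes the mean of the observed values at that site among the $k = 5$
samples most correlated (Pearson, pairwise-complete) with the target sample.
Observed cells are never modified. kNN over sample correlation is the
documented behavior class of the aggregation tools used for such matrices;
$k = 5$ is a standard small-cohort choice.

In the matrix, forward and reverse records of a dyad are kept as **distinct
sites** — this mirrors the per-site matrices of the upstream tools and loses
no information. For site-level inference, however, the natural unit is the
dyad: both strands measure the same cytosine pair, and averaging them
(`collapse_dyads()`) halves the binomial noise variance. The age-association
analyses below therefore operate on dyad means; the matrix representation
keeps strands separate so either choice remains available.

# Positional profiles

All interval arithmetic is internally 0-based half-open; CGmap positions are
1-based, BED half-open 0-based, GFF3 1-based closed, with conversions
centralized at ingestion. A site exactly at the TSS belongs to the first
body bin, not the flank.

`metagene_profile()` cuts each flank into `n_flank_bins` fixed-width bins
(default 30 bins over 3 kb — roughly 100 bp resolution, matching the flank
scale) and the gene body into `n_body_bins` equal-fraction bins (default
40). The bin counts are package choices, exposed in `metagene_params()`;
nothing upstream fixes them. Minus-strand genes are flipped so bin 1 is
always the far 5' end; genes shorter than `n_body_bins` positions are
skipped with a warning; flanks running off a contig edge are truncated, not
dropped.

Per-bin aggregation is **gene-averaged** by default (mean over genes of the
per-gene bin means) so long or CpG-dense genes do not dominate; site-pooled
aggregation is available via `aggregation = "site"`.

Decile stratification ranks genes by the unweighted mean of covered CpG
site levels in the gene body (TSS..TES). Coverage weighting is available in
`region_mean_methylation()` but is not the default: with a 10-read floor
already applied, the site mean is the simpler and more robust statistic,
and the convention upstream of the package is ambiguous. Ties are broken by
(mean descending, gene id ascending); with $n$ genes and 10 groups, the
remainder $n \bmod 10$ is spread from the top group down.

Exon-rank profiles are restricted to genes with at least five exons
(`min_exons = 5`) and report ranks 1–4, each scaled to equal-fraction bins;
exon rank follows transcription order, so rank 1 of a minus-strand gene is
its most 3' genomic exon. The exon-1 junction profile uses a ±100 bp
window in 10 bp bins, stratified by exon-1 mean-level deciles; single-exon
genes have no junction and are excluded.

The exon-vs-intron comparison pools per-region means across genes
(two-sided rank-sum); a paired per-gene variant is available via
`paired = TRUE` since the pooling convention is genuinely open. Conditional
means over regions with non-zero methylation are reported alongside, as the
two summaries answer different questions (how much of the genome is
methylated at all vs how methylated the methylated part is).

# Age-association machinery

## Permutation test

`permutation_test_positions()` computes, per position, the observed group
mean difference and compares it with differences under random relabelings
of the samples (group sizes fixed). Labels are permuted **jointly across
positions** — one relabeling per draw — which preserves the cross-position
dependence structure; per-position independent permutation is the other
defensible reading of the upstream description, but joint relabeling is
what "reassigned sample labels" most plainly means and is implemented here.
Draws are sampled with replacement from the assignment space; with the
default 100,000 draws against $\binom{17}{9}$-scale spaces this is standard
practice. The reported p is the plain proportion $b/n$ (so $p = 0$ is
possible); a $(b+1)/(n+1)$ correction is available via
`p_correction = "add_one"`.

One numerical subtlety: "as extreme as" must count exact ties, including
the identity relabeling. The observed and permuted statistics travel
through different BLAS code paths and can disagree in the final ulp, so the
comparison applies a $10^{-12}$ tolerance — far below the resolution of any
methylation level at realistic coverage.

## The LOOCV Lasso clock

`fit_clock_loocv()` holds out each sample in turn, fits
$\text{age} \sim \text{L1-penalized linear model on CpG levels}$ on the
rest (penalty chosen by inner leave-one-out CV over a log-spaced grid,
$10^{1}$ to $10^{-3}$), and predicts the held-out age. Performance is the
Pearson correlation between held-out predictions and true ages.

A caveat that matters for small cohorts: under a null matrix the inner CV
correctly shrinks most folds to the intercept, and an intercept-only fold
predicts $\overline{\text{age}}_{-i}$ — which is *perfectly anti-correlated*
with the held-out age. Cross-validated null predictions therefore show
spurious negative correlations that a two-sided test can flag as
"significant". Since a clock has predictive skill only when the correlation
is positive, the headline `p_value` is one-sided for positive association;
the two-sided value is reported as `p_two_sided` for completeness.

Ages enter in days. For cohorts whose metadata give ranges (e.g. "22 to 27
days"), the encoding is the user's choice; the cohort generator assigns
specific days within each range, and for real range-only metadata the
midpoint is the recommended default.

## Gene-level regression

`gene_age_regression()` is ordinary least squares of per-gene mean level on
age with two-sided slope tests and Benjamini–Hochberg adjustment across
genes (FDR 0.05 is the conventional cut; the function reports q-values and
leaves the threshold to the caller). Constant genes are reported with slope
0 and $p = 1$, flagged degenerate, rather than dropped.

## Embedding

`embed_samples()` wraps UMAP (single-threaded, seeded, so runs are
reproducible). No separation by age group is promised or required — an
absence of clustering is itself a finding for cohorts without strong
age-associated methylation.

# The synthetic cohort generator

The generator exists so that every downstream stage has a ground truth. It
emulates, at reduced genome scale, the statistical structure of a
17-sample, three-age-group bisulfite study of a sparsely methylated
invertebrate genome:

* **Cohort design** (`cohort_design()`): 17 samples — young (9 days,
  $n=5$), mature (22–27 days, $n=6$), old (51–58 days, $n=6$). The
  three-group split is fixed by the study design; the 5/6/6 allocation is
  the package's choice where the exact split is not recorded.
* **Genome**: 2 nuclear contigs of 100 kb plus a 15 kb mitochondrial
  contig, CpG dyads every ~45 bp, two non-CpG cytosines per dyad. These
  sizes keep a full cohort simulation under a second while leaving several
  thousand dyads per sample; they are deliberately far below a real
  assembly (hundreds of Mb), which is why the package's tests demonstrate
  *statistical* behavior, not production-scale performance.
* **Coverage**: negative binomial with mean 60 and dispersion 8 — the
  long-tailed depth distribution characteristic of whole-genome bisulfite
  libraries; a Poisson would be too narrow. The mitochondrial contig gets
  4x that depth (`mito_coverage_factor`): mitochondrial copy number
  inflates its coverage in real libraries, and that extra depth is exactly
  what makes the control contig informative — at 60x, three quarters of
  unmethylated sites show zero methylated reads and the median level
  degenerates to 0.
* **True levels**: background CpG level 0.01; exonic CpGs get an additive
  boost $m_g \cdot b \cdot w(r)$ where $w(r)$ peaks at exon rank 3
  (0.55, 0.85, 1, 0.7, then decaying), $b = 0.05$, and
  $m_g \sim \text{LogNormal}(\log 0.3,\ 1.6)$ is a per-gene multiplier
  giving decile stratification real signal. These three numbers were
  calibrated once against the global CpG summary statistics such data
  display (mean ~2%, ~6–9% of sites above 0.05, ~1% above 0.2, a few per
  mille above 0.8) and then frozen. Non-CpG and mitochondrial cytosines
  have true level 0. Introns sit at background level; the exon/intron
  contrast and the junction step-down follow from the exon boost alone.
* **Age-CpGs**: `n_age_cpgs` dyads get true level
  $0.05 + \beta \cdot \text{age(days)}$ with $\beta$ =
  `age_effect_per_day` (0 for null cohorts). A modest base level keeps the
  binomial noise small where the signal lives.
* **Per-sample structure**: biological noise (sd 0.01) is drawn per dyad
  per sample and shared by both strand records, so symmetry is preserved;
  the true between-animal variance of such cohorts is not well established,
  which is why it is an exposed parameter rather than an asserted value.
  Per-sample seeds are a deterministic hash of (master seed, sample id), so
  cohorts are byte-reproducible and samples are independent of cohort
  order.

What the generator does **not** emulate: read-level chemistry (no FASTQ, no
per-read conversion), nuclear copies of mitochondrial DNA (which in real
data contaminate the control contig), repeat elements, chromatin-driven
coverage bias, and any dependence between neighbouring dyads. Passing tests
on generator output therefore validate the estimators' statistical
contracts, not their robustness to those real-data complications.

# Numerical and degenerate-input choices

* CGmap validation is strict: 8 fields, $0 \le mc \le cov$,
  $level = mc/cov$ (tolerance $10^{-6}$ for rounded inputs), dinucleotide
  CG iff context CG; errors name the offending line.
* Rank-sum comparisons use the exact null distribution when both sides have
  $\le 25$ observations and no ties; otherwise the tie-corrected normal
  approximation without continuity correction, so identical inputs give
  exactly $p = 1$. Zero rank variance (all observations tied) is reported
  as $p = 1$, since every relabeling produces the same statistic.
* Undefined correlations (constant vectors, fewer than 2 shared sites) are
  returned as NA with a warning — never silently 0.
* Empty regions, absent contexts and skipped positions are flagged, not
  dropped silently.

# Problem sizes used by the tests and acceptance script

The test suite and `scripts/acceptance.R` run the full pipeline on
generator cohorts at the default genome scale (two 100 kb contigs + mito;
~9,500 CG-context matrix sites across 17 samples), with 5,000 permutations
for calibration and power checks and 20,000 for the exhaustive-oracle
equivalence check (whose exact reference enumerates all
$\binom{6}{3} = 20$ or $\binom{7}{4} = 35$ relabelings). The defaults in
the package (`n_permutations = 100000`) remain the recommended setting for
real analyses.

# Known limitations

* The dyad pairing trusts the CGmap strand column and position arithmetic;
  it does not consult a reference genome, so miscalled strands in the input
  propagate.
* Imputation assumes at least one observed value per site (guaranteed by
  the aggregation rule at $f \ge 0.5$) and a meaningful sample correlation
  structure; with very few samples the neighbour ranking is noisy.
* The clock's inner CV is leave-one-out on already-small training folds;
  with 17 samples its penalty choice is variable. This mirrors the
  real-data situation rather than hiding it.
* UMAP coordinates are reproducible only for a fixed seed and thread count;
  the package pins both.
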