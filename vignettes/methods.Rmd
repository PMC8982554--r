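---
title: "Methods: differential enhancer expression, target linking and allelic TFBS scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: differential enhancer expression, target linking and allelic TFBS scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

enhancerDE implements a pan-cancer enhancer-RNA analysis over paired
tumor/normal expression cohorts. The pipeline has five analysis stages,
each exposed as ordinary functions and composed by `run_pipeline()`:

1. **Differential expression** of enhancers and genes per cohort:
   prevalence filter, log2 fold change of group means, Welch t-test,
   Benjamini–Hochberg (BH) control.
2. **Expression breadth**: classification of each feature as
   tissue-specific, ubiquitous, or other by the number of cohorts in which
   it is expressed.
3. **Target linking**: DE enhancer → DE gene candidates by promoter
   geometry within ±100 kb of the enhancer center, screened by Spearman
   coexpression with BH control, then partition of DE enhancers into
   regulated and nonregulated.
4. **Over-representation**: exact hypergeometric test of linked DE genes
   against gene-set collections.
5. **Allelic TFBS scoring**: SNPs mapped into extended DE enhancers and
   classified per transcription factor as binding-site gain, loss, or
   unchanged between allele-specific PWM scores.

A synthetic-data generator (`simulate_dataset()`) produces all inputs with
planted ground truth, so every stage is testable without any download.

# Coordinates and input contracts

All internal coordinates are BED-style 0-based half-open. SNP positions
are 1-based on input (the VCF convention) and converted on ingest
(`pos0 = pos - 1`). Abutting half-open intervals do not overlap.

Every coordinate-bearing input must be on one genome assembly; the
package does not lift coordinates between assemblies. `read_enhancer_bed()`
and `read_snp_table()` accept an optional assembly tag and `map_snps()`
refuses mismatching tags.

The gene annotation table must be pre-collapsed to one TSS per gene id.
Which transcript's TSS represents a multi-isoform gene is a genuinely open
annotation question, so it is deliberately left to the caller rather than
guessed inside the package.

Enhancers are treated as unstranded (bidirectionally transcribed), and
their search windows are symmetric, so enhancer strand never enters any
computation. The center of an even-length enhancer is the floor of its
midpoint — a deterministic, conventional tie-break.

# Differential expression

Within one cohort a feature is *testable* when it is expressed (value
strictly above `expressed_threshold`, default 0) in at least
`prevalence_min` (default 10%, boundary inclusive) of the tumor samples
**or** of the normal samples. The disjunctive reading keeps a feature seen
only in normal tissue testable as a down event; a conjunctive reading
would silently discard exactly the features with the strongest losses.

For each testable feature:

- `log2fc = log2((mean_tumor + c) / (mean_normal + c))` with pseudocount
  `c = 0.01` (RPKM-scale units). The pseudocount guards dropout-heavy
  features against division by zero while being small relative to typical
  expression; it cancels exactly for all-zero features.
- The p-value comes from the two-sided **Welch** t-test (Satterthwaite
  degrees of freedom). Tumor and normal sample sets in this design are
  unpaired and usually unbalanced, which makes the unequal-variance
  statistic the defensible default; a pooled-variance Student variant is
  available via `t_test_pooled`. When both groups are constant the
  statistic is undefined and the conventions p = 1 (equal constants) and
  p = 0 (unequal constants) apply.
- q-values are BH-adjusted **within one cohort and one feature class**
  (enhancers separately from genes). Sharing a family across classes would
  let the much larger gene family dominate the enhancer discoveries.
- The call is `up` iff `log2fc >= 1` and `q < 0.05`, `down` iff
  `log2fc <= -1` and `q < 0.05`, otherwise `ns`. Both gates are needed: a
  tiny q with a sub-threshold fold change stays `ns`.

On the synthetic null (zero-inflated log-normal data, n = 50/50) the
Welch test is mildly conservative — the test suite measures an empirical
type-I error of about 0.04 at nominal 0.05 over 10 000 features — a known
consequence of skew and the point mass at zero, and the conservative
direction for discovery.

# Expression breadth

A feature is *expressed in a cohort* under the same prevalence rule as
candidate filtering, restricted to one condition (tumor or normal).
Consistency with the testability rule was chosen deliberately; using a
different criterion for breadth would make the regulated-by-ubiquitous
cross-tabulation incoherent. With `k` of `n` cohorts expressing a feature:
`k = 1` is tissue-specific, `k = n` ubiquitous, anything between is other;
features expressed nowhere are excluded from classification and reported
separately. Tumor and normal panels are computed separately.

Reported percentages are rounded half away from zero — two decimals for
the cross-tabulation, one for cohort SNP shares — matching the conventions
of published summary tables.

# Target linking

A gene promoter is the strand-aware window 0.5 kb upstream to 1 kb
downstream of its TSS, clamped at position 0. A (DE enhancer, DE gene)
pair is a candidate when the promoter overlaps the ±100 kb window around
the enhancer center (half-open semantics). The overlap join runs on
GenomicRanges; the test suite checks it against a quadratic all-pairs
search.

Candidates are screened by Spearman correlation across the cohort's
**tumor** samples. Restricting to tumor samples is the default because
pooling tumor with normal lets the differential shift itself manufacture
correlation between any two DE features, inflating links; joint
computation remains available via `link_samples = "all"`. The screen is
one-sided positive (`rho >= 0.3`), consistent with enhancers as positive
regulators; an absolute-value mode is available via `link_use_abs_corr`.
BH runs within one cohort across all candidate pairs, and a link requires
`q < 0.05`.

The Spearman p-value is exact — the full permutation distribution of rho,
ties included — for n ≤ 8, and uses the t approximation with n − 2 degrees
of freedom above that. The cutoff is set where exhaustive enumeration
stops being proportionate (the permutation count grows factorially: 9!
already exceeds 3.6 × 10^5 × n work) and where the approximation error is
far below any decision threshold. Pairs with zero rank variance have no
defined correlation and are dropped with a logged count.

Regulated DE enhancers are those with at least one significant link; the
partition is exhaustive and disjoint by construction. The regulated vs
nonregulated expression comparison uses the two-sided Wilcoxon rank-sum on
per-enhancer mean tumor expression — robust to the heavy right skew of
expression data, where a t-test's level would be at the mercy of outliers.

# Over-representation

The statistic is the exact upper-tail hypergeometric probability
P(X ≥ k), accumulated in log space (`lchoose` + log-sum-exp) so that large
universes cannot underflow. The default universe is the set of genes
passing the prevalence filter in at least one cohort — the genes that
*could* have been discovered — rather than the whole annotation, matching
standard over-representation practice; it is a function argument, not a
constant. Gene sets are intersected with the universe, empty intersections
are dropped with a message, and BH runs across the retained sets.

# Allelic TFBS scoring

DE enhancers are extended by 0.5 kb on each boundary and SNPs mapped into
the extended regions (half-open; multi-mapping SNPs produce one event row
per enhancer). For each SNP × motif:

- Position frequency matrices become PWMs with a total pseudocount of 0.8
  per position distributed by the background composition
  (Wasserman–Sandelin convention; uniform background by default).
- The window score is the log2 odds sum over positions. The best score is
  taken over every window overlapping the SNP, on both strands, under the
  reference and the alternate allele. The supplied sequence must carry the
  reference allele at the SNP position; a mismatch is an error naming the
  rs id. Windows containing ambiguous bases are skipped.
- Each best score converts to an exact background tail probability: the
  null distribution of a single window score is computed by convolving the
  per-position 4-point score distributions on a fixed grid of 10^-3 bits.
  Because each of the L per-position scores rounds to the grid
  independently, the tail lookup allows the accumulated tolerance of
  L × 10^-3 / 2 bits — scores within it count into the tail, the
  conservative direction for a binding call.
- A motif is *bound* under an allele when its tail probability is at or
  below `tfbs_p_max` (default 10^-4). **Gain** means only the alternate
  allele is bound, **loss** only the reference; everything else is
  unchanged (retained, flagged). Swapping ref and alt provably swaps gain
  and loss and negates the score delta.

This per-allele exact-threshold scheme deliberately replaces
importance-sampled p-values for the score *change* between alleles. The
per-allele formulation is exactly computable (and exactly testable against
4^L enumeration), and its binding-call semantics — "a site exists under
one allele and not the other" — is the quantity the downstream summaries
count. The significance threshold for declaring a functional site is
exposed as configuration rather than hard-coded, since no canonical value
exists.

# The synthetic-data generator

The generator emulates the *structure* the analysis assumes — 13 paired
tumor/normal cohorts by default, RPKM-scale continuous values — with known
truth:

- **Baseline noise** is log-normal (meanlog 1, sdlog 1), not negative
  binomial: the pipeline consumes normalized continuous values, not
  counts.
- **Planted DE features** (default 10% per cohort, |log2FC| = 2) have
  their tumor mean scaled by 2^(±log2FC).
- **Dropout** is detection-limit censoring: values below the baseline
  distribution's 20% quantile are recorded as 0. Zeros therefore
  concentrate in low-abundance measurements, as in real RPKM data, and the
  expected zero share at baseline equals the dropout parameter. An
  alternative — zeroing positions independently at random — was rejected
  because it shreds planted rank correlations (a planted Spearman 0.6
  drops to roughly 0.24 under 20% independent dropout), leaving no
  recoverable signal for the linking stage to find; value-dependent
  dropout is also the mechanistically realistic model. A side effect worth
  knowing: censoring hits a down-shifted tumor group hardest, so observed
  |log2FC| of down-planted features overshoots the planted magnitude,
  while up-planted features are recovered unbiasedly.
- **Planted links** (Spearman target 0.6) couple an enhancer–gene pair
  through a shared latent Gaussian factor (Gaussian copula); the latent
  Pearson correlation is `2 sin(pi rho / 6)` so the rank correlation hits
  the target. Pairs are drawn from the distance-eligible pairs of the
  generated layout, so they satisfy the ±100 kb rule by construction, and
  both members are planted as concordant **up** events: the screen is
  one-sided positive, and a down-planted member would sit mostly below the
  detection limit with no rank signal left to recover.
- **Motifs and SNPs**: demo motifs concentrate their information in an
  8-position core (one strongly preferred base per core position, padded
  with exactly uniform positions), placing the consensus just inside the
  default binding threshold and a single core mismatch just outside it —
  the regime where one SNP can create or destroy a site. A *loss* SNP
  mutates the highest-information position of an embedded consensus; a
  *gain* SNP restores a pre-mutated consensus; *neutral* SNPs sit at least
  one motif length from any embedded motif.

What the generator does **not** emulate: batch effects, copy-number
confounding, library-size artifacts, read-level noise, linkage between
SNPs, or realistic motif databases. Passing recovery tests therefore
demonstrates the pipeline's correctness and statistical behavior under its
stated model, not performance on real TCGA-scale data, where effect sizes
are smaller and confounding is real.

# Problem sizes and determinism

The recovery checks in the test suite run at deliberately modest sizes:
13 cohorts × (50 + 50) samples with 200 enhancers and 400 genes for DE
recovery; 3 cohorts × (100 + 100) samples for link recovery at n = 100;
10 000 features for null calibration; 1000 simulations for the rank-sum
level check. These sizes put Monte-Carlo error well below the decision
margins while keeping the default test run fast.

Every generator is deterministic given its seed, and the pipeline itself
contains no randomness, so `run_pipeline()` on fixed inputs is
byte-identical across runs — the manifest records the configuration,
input checksums and per-stage counts, and contains no timestamps for
exactly this reason.

# Known limitations

- The t-test on zero-inflated skewed data is mildly conservative at
  moderate n (see above); a rank-based DE option is not implemented
  because the fold-change gate already dominates calls at realistic
  effect sizes.
- Correlation-based linking cannot distinguish direct regulation from
  co-regulation by a shared driver; the distance window bounds, but does
  not eliminate, spurious candidates.
- The per-allele TFBS scheme ignores the magnitude of the score change
  when both alleles are bound (or neither is); such events are retained as
  `unchanged` rather than ranked.
- Indels, multi-allelic variants and assembly lifting are out of scope.
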