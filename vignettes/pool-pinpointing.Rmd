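---
title: "Decoding and filtering two-dimensional overlapped pool sequencing"
author: "poolPinpoint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding and filtering two-dimensional overlapped pool sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(poolPinpoint)
```

## The design and its decoding model

In a two-dimensional overlapped pooling design, N = R × C DNA samples
are arranged in a matrix and pooled twice, along rows and along columns.
Each sample contributes to exactly one pool per axis, and any two pools
share at most one sample. A pool of m diploid individuals contains 2m
haplotype copies ("pool ploidy"), so a heterozygous variant carried by a
single member has expected allele fraction 1/(2m); the *allelic
coverage* (pool depth divided by pool ploidy) is the effective per-copy
depth. The reference design in this package is a 10 × 10 matrix
sequenced to ~2000× per pool, i.e. 100× allelic coverage.

The decoder rests on one combinatorial fact: a variant carried by
exactly one individual appears in exactly one row pool and one column
pool, and in no other pool of either axis. `assignVariants()` therefore
computes, per row, the variant keys unique to that row against all other
rows, likewise per column, and assigns each key in
`unique(row i) ∩ unique(col j)` to the individual at cell (i, j). The
converse also holds on error-free pools: a variant with two or more
carriers is present in at least two pools of at least one axis, fails
the uniqueness test there, and is never assigned. This decodability
property — assignment equals the single-carrier set — is asserted in the
test suite by comparing the decoder against a brute-force
carrier-counting oracle on random cohorts over random matrix shapes.

Identity throughout is the normalized variant key
`(chrom, pos, ref, alt)`. Genotypes are deliberately ignored: pool
genotype calls at ploidy 20 are unreliable, and the design only needs
presence/absence. Indel keys are put in leftmost-parsimonious form by
the standard trim-and-shift canonicalization (shared trailing bases
trimmed with re-anchoring on the preceding reference base, then shared
leading bases trimmed while both alleles keep one base). One consequence
for two-caller gold standards: representations of the same indel that
differ only by placement merge into one key (HIGH confidence), while
genuinely distinct representations stay distinct and become two LOW keys
— no fuzzy matching is attempted. Symbolic alleles (`<DEL>`, breakends)
and spanning-deletion `*` alleles are rejected: the method's scope is
SNVs and small indels.

## Gold standards, theoretical pools, private variants

Per-individual call sets from two independent germline callers are
partitioned by `confidencePartition()` into HIGH (called by both — the
intersection) and LOW (called by exactly one — the symmetric
difference). Downstream constructions take a confidence filter
argument: validation baselines conventionally use HIGH only, while
filter-training labels use the HIGH ∪ LOW union, so that a pool call
matching *any* gold-standard call of that pool's membership counts as
concordant. Both conventions are selectable at every call site because
the two uses genuinely differ: a strict truth set for benchmarking, a
permissive one for labeling (a call echoed by either caller is unlikely
to be a sequencing artifact).

`buildTheoreticalPools()` unions the (filtered) member call sets of each
row and column — the variant content a pool would show under perfect
sequencing — and `privateVariants()` keeps the keys with exactly one
carrier among the matrix samples. These two derived objects are always
recomputed from the gold standard rather than stored, so they cannot go
stale when the layout or filter changes.

## The simulator: what it emulates, and what it does not

The simulator is variant-level, not read-level. It models the quantities
the decoder and filter actually consume — per-pool detection and
annotations — rather than reads:

* **Cohort**: `nSites` polymorphic sites on a synthetic contig, allele
  frequencies i.i.d. from Beta(`afAlpha`, `afBeta`) (default
  Beta(0.3, 8), median well under 1%, so a realistic fraction of sites
  is private to one individual), genotypes drawn per individual with
  Hardy–Weinberg probabilities. The default `nSites = 800` is a
  desk-scale stand-in for a gene panel; population structure and
  relatedness are not modeled.
* **Pooled sequencing**: per pool of m individuals, site depth
  `Poisson(2m · allelicCoverage)`; alt reads
  `Binomial(depth, (ac/2m)(1−e) + (1−ac/2m)e/3)` with summed copy
  number `ac` and per-base error `e` (default 10⁻³). A call is emitted
  when alt reads ≥ `minAltReads` (3) and the alt fraction ≥
  `minAltFraction` (0.015). The fraction threshold is deliberately close
  to the singleton fraction of large pools (1/48 ≈ 0.021 at 24×24), so
  large matrices sit near the detection limit, as they do in practice.
* **Indel dropout**: indels additionally fail detection per pool with
  probability `min(0.9, indelDropout · m/10)` (default `indelDropout` =
  0.10). The mechanistic causes of pooled indel loss — alignment
  ambiguity in low-complexity regions, growing with the number of
  competing haplotypes — are upstream of a depth model, so they are
  summarized by this one pool-size-scaled parameter. The default was
  fixed at design time to place large-matrix indel sensitivity in the
  0.6–0.8 band characteristic of 24 × 24 designs, and is not revisited.
* **Artifacts**: each pool receives `Poisson(fpSiteRate · nSites)`
  artifact calls (default rate 0.15) drawn from a shared panel of
  recurrent error-prone sites sized at half the true-site count.
  Recurrence matters: artifacts striking several pools fail the
  uniqueness test, which is why raw pool-level FDR (~0.2–0.35 under the
  defaults) collapses to ~0.05–0.1 at the pinpoint level — the decoder
  is itself a filter.
* **Annotations**: every emitted call carries synthetic technical
  annotations drawn from class-conditional lognormal/gamma/normal
  families (true calls: high QD ≈ 20, MQ ≈ 60, low FS/SOR, centered
  rank sums; artifacts: low QD ≈ 4, inflated FS/SOR, negative rank
  sums), with rank sums missing at rate 0.2 to exercise imputation.
  These distributions are a modeling device, clearly synthetic: they are
  more cleanly separable than real caller annotations, so end-to-end
  filter results on simulated data are an upper bound on real-data
  behavior, and passing tests demonstrate the machinery, not field
  accuracy.

Every stochastic step derives from the config seed through a fixed
integer recurrence, making runs bit-reproducible; the seed recurrence
stays inside 32-bit range.

## Filter training and threshold calibration

Calls are labeled per pool by membership of their key in the pool's
truth set (`labelCalls()`); missed truth variants yield no rows. Feature
handling follows common practice: all-constant features are excluded;
correlation pruning drops the alphabetically later member of any pair
with |r| ≥ 0.9 (the threshold is a convention, configurable); mRMR
selection uses the F-statistic relevance over mean absolute correlation
redundancy quotient, deterministically.

Training uses repeated nested cross-validation — 5 repetitions, 10
stratified outer folds, 5 inner folds — so 50 outer models per run.
Hyperparameters are chosen on inner folds only (scored by F1 at
threshold 0.5, with small documented grids: ridge penalty for LR,
minimum node size for RF, tree depth for XGB, component count for GMM);
each row receives an out-of-fold probability in every repetition; the
final model refits the full table with the modal hyperparameters across
the 50 selections. Class imbalance is handled by balanced class weights
rather than resampling, keeping predicted probabilities directly
calibratable. GMM is a supervised wrapper — one diagonal-family mixture
per class, posterior class probability under balanced priors — since it
is used here as a classifier among classifiers. Missing feature values
are imputed with training-partition medians stored in the model;
rank-sum annotations are routinely absent and must never silently drop a
call. The shipped pipeline default is LR for SNVs and RF for indels;
all four families remain trainable for benchmarking.

Two operating points are calibrated on the pooled out-of-fold
probabilities by exhaustive enumeration of observed probabilities as
candidate thresholds: `t_F1` maximizes F1 (ties resolved toward the
smaller threshold, favoring sensitivity), and `t_S99` is the largest
candidate retaining ≥ 99% sensitivity, falling back to pass-all when
none qualifies. Note `t_S99` may exceed `t_F1` on well-separated data:
it is the *strictest* threshold compatible with the sensitivity target.

## Evaluation conventions

Metrics are computed from summed confusion counts (aggregate-then-
divide): sensitivity TP/(TP+FN), precision TP/(TP+FP), FDR = 1 −
precision, F1 the harmonic mean. Zero denominators leave a metric
explicitly undefined (`NA`) rather than fabricating 0/0 = 0; F1 is
defined as 0 when precision and sensitivity are both defined and zero,
keeping it usable for ranking. Values are held at full precision and
rounded only for output, half away from zero to 3 decimals. Each pool is
an independent comparison: a variant appearing in both a row and a
column pool contributes to both comparisons, which is stated rather than
hidden. Pinpoint-level evaluation scores (sample, key) pairs, so a
variant assigned to the wrong individual is an FP there and an FN at the
true carrier. Bootstrap intervals resample call-level outcome events
(the TP/FP/FN union) with replacement, n = 1000, reporting 2.5/97.5
percentiles; undefined replicates are excluded and counted. Resampling
category counts via a multinomial draw is used internally — it is
exactly the bootstrap distribution of event resampling, at a fraction of
the cost.

## Numerical and design choices

* Coordinates are 1-based and fully closed, as in VCF.
* Per-allele (comma-separated) INFO values take the element matching the
  split allele; scalars are copied to every split key. Records with at
  least one called alt allele are kept regardless of genotype
  completeness, since identity is genotype-free anyway.
* Assigned calls emit the row pool's annotations, with the column
  pool's under a `col.` prefix: both observations are preserved and no
  merge rule is invented.
* Decoding is pure set algebra, so iteration order cannot affect
  results; a shuffled-order equivalence test asserts this.
* Empty cells of partially filled matrices can attract uniqueness
  intersections; these are warned about and parked in
  `unassignedShared`, never assigned.
* The command-line wrapper defaults to filtering before pinpointing when
  models are supplied, matching the pipeline ordering in which
  filtration precedes assignment; both paths (filtered and raw) are
  available programmatically.
* Test problem sizes were chosen to keep the whole suite at a few
  minutes on one CPU while leaving every Monte-Carlo comparison with
  comfortable margins: grids use 500–600 sites and 2–3 replicates, the
  end-to-end filter check uses the full 800-site reference design once.

## Known limitations

* The simulator's annotation classes separate more cleanly than real
  GATK annotations; filter FDR ≈ 0 on synthetic pools should not be
  extrapolated to real data.
* Indel dropout is a single summary parameter, not a mechanistic model
  of low-complexity-region alignment failure; only qualitative
  size/coverage trends are meaningful, not absolute indel sensitivities.
* Exact-key matching after normalization will not reconcile complex
  multi-variant representations of the same haplotype; haplotype-aware
  comparison is out of scope.
* Variants shared by ≥ 2 individuals in the matrix are structurally
  unassignable; as matrices grow, the private fraction shrinks, which is
  the fundamental sensitivity/cost trade-off of the design.
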