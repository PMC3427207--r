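---
title: "Methods and modelling choices in regulonscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and modelling choices in regulonscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The question and the model

`regulonscan` asks whether a transcription factor's own expression change
between two sample groups plausibly drives expression differences of its
predicted target genes, and whether that TF-target relationship replicates
in an independent cohort. The underlying assumption is the classical
*trans*-regulation argument: if a TF's mRNA concentration tracks its
activity, genes it regulates should co-vary with it, and a group-level
change in the TF should propagate to its regulon. None of the statistics
below establishes causality; they establish *non-random association*
between a TF's profile and its annotated regulon, calibrated against
permutation nulls.

The pipeline has seven analytic stages, each usable on its own:
preprocessing, permutation-calibrated differential expression, effect
sizes, the TF regulatory-effect scan, cross-cohort correlation of
correlations (CoC), conserved-motif target prediction with three
authenticity nulls, tissue-specificity comparison, and category enrichment
with resampling FDR.

# Preprocessing

Expression matrices are log2-transformed (pseudocount 1 for counts, 0 for
continuous arrays) and quantile-normalized against the rank-wise mean of
the sorted columns. Tied values within a column receive the mean of the
reference quantiles of their tied ranks — the standard dialect; on
tie-free data the step is exactly idempotent, with ties only approximately
so.

Detection filtering retains a gene if it is detected in at least half of
all samples **or** shows significantly uneven detection across groups
(Fisher's exact test at p < 0.1). The unevenness clause keeps genes
expressed in only one group — exactly the genes a differential analysis
must not discard. We read the two published criteria as a union; the
conjunctive reading would drop group-specifically expressed genes, which
contradicts the stated motivation of the second criterion. The unevenness
test is a plain Fisher test rather than a noncentral hypergeometric model:
the decision semantics are the same and the noncentral odds weights are
not identifiable from the description.

Batch effects are removed by subtracting each batch's per-gene mean. This
exactly zeroes within-batch means but consumes degrees of freedom the
downstream t-test does not know about, so nominal p-values after batch
centring are slightly anticonservative. This is deliberate: the error rate
that matters is controlled by the permutation calibration, which sees the
same centring.

Two cohorts are combined by two-stage z-scoring (within cohort, then
across the concatenated samples), restricted to shared genes; zero-variance
genes are dropped with a warning. Sample SDs use the n−1 denominator
throughout.

# Permutation-calibrated FDR

Group labels are permuted (sampled with replacement from the permutation
group, identity excluded), the per-gene test is recomputed each round, and
for every candidate cutoff on the grid of observed p-values the FDR is
estimated as median(permutation count) / observed count. The selected
cutoff is the **largest** grid value with estimate at or below the target
(default 10%), ties broken toward the smaller cutoff. We select on the raw
ratio: the ratio is not monotone in the cutoff at desk scale because the
integer-valued median jumps, and monotonizing before selection propagates
an early jump and can empty the significant set. A running-maximum copy of
the curve is returned for diagnostics.

The per-gene test is pluggable; the default for both array-like and
count-like cohorts is the pooled t-test on normalized values (for two
groups it coincides with the one-way ANOVA F-test). A negative-binomial
count test is out of scope by design: the permutation calibration, not the
test family, controls the error rate.

# Effect sizes

`d = (M1 − M2)/SDp` with the pooled SD formula, and |d| > 0.8 as the gate
for "modest" effects. Two properties of this estimator shape the test
design and are easy to forget:

* At n = 6+6 the estimator is noticeably biased upward
  (E[d̂] ≈ 1.08·d at df = 10) and noisy (SD ≈ 0.67 at d = 1.5). The
  probability that a gene planted at d = 1.5 clears the 0.8 gate is
  1 − pt(0.8√3, df = 10, ncp = 1.5√3) = 0.883 — *not* ≥ 0.95. One
  acceptance clause demands 95% recall in exactly this world; it is
  asserted as stated and fails honestly.
* Generative self-consistency of the synthetic module is therefore checked
  at n = 20 per group, where the Hedges-type bias is ~2%.

# The regulatory-effect scan

For each (TF, motif) regulon whose TF passes the effect-size gate, Pearson
correlations between the TF profile and each eligible target are compared
with correlations to eligible non-targets (genes annotated as targets of
*other* TFs) by a two-sided rank-sum test at p < 0.01. Correlations are
computed across all samples pooled over groups: the between-group shift is
part of the signal being traced, and pooling maximizes the tested
contrast. Regulons with fewer than 5 eligible targets (a default the
source procedure leaves open) are reported as untestable rather than
dropped. The rank-sum p is exact (no ties, both sizes ≤ 25) or
normal-approximated with tie and continuity corrections; both routes are
checked against an exhaustive enumeration oracle in the tests.

Global calibration permutes TF-target relationships: a random bijection of
the eligible annotated genes is applied to every regulon's target set,
which preserves target-set sizes *and* overlap structure, and the number
of passing TFs is recorded per round. The global p is the fraction of
rounds reaching the observed count. A structural consequence: with ~20
testable regulons at per-regulon level 0.01, a permutation round reaches a
count of one in ≈ 1 − 0.99²⁰ ≈ 18% of rounds, so a *single* passing TF can
never be globally significant at 0.05 — only multiple passing TFs can.
The corresponding acceptance clause (one driver, global p < 0.05) is
asserted as stated and fails honestly.

# Correlation of correlations

Per shared eligible target, r(TF, target) is computed independently in two
cohorts; Spearman correlation between the two r vectors (≥ 3 shared
targets) measures cross-cohort consistency. Two modelling points:

* If all targets are coupled with the same sign and strength, the
  per-target r values differ only by noise, and their cross-cohort
  Spearman correlation is *centred at zero* even for a real driver. CoC
  has power only when the regulon has structure — mixed activation and
  repression, or heterogeneous coupling. The synthetic generator therefore
  exposes `sign_mix`, and CoC recovery tests use sign-mixed regulons.
* A large shared between-group shift makes *any* consistently shifted
  gene set CoC-consistent (both cohorts' r values inherit the group
  structure with matching signs). The CoC permutation null is therefore
  informative only when within-group coupling dominates the shift; its
  test world uses a small planted shift (d = 0.5). On strongly shifted
  worlds the permutation null is honest but unable to distinguish a true
  regulon from any other consistently shifted gene set — a caveat that
  applies equally to real data.

# Motif scanning and the three authenticity nulls

PWM similarity follows the MATCH convention: per-position information
weights I(i) = Σ_b f(i,b)·ln(4 f(i,b)) (0.25 pseudocount per base), scores
min-max normalized so a consensus match scores exactly 1 and the worst
sequence 0, computed for the full matrix and for the core positions.
Default operating point min_score = 0.85, min_core_score = 0.90 — the
published per-matrix cutoff profiles are proprietary, so these are
configurable defaults, and the planted-consensus tests are insensitive to
the exact value. Minus-strand matches are scored against the
reverse-complemented weight matrix and reported at plus-strand leftmost
coordinates, TSS-relative, downstream positive. Windows containing N are
skipped. A site's conservation summary (coverage, mean over covered
bases) is strandless. A site is "conserved" when coverage ≥ 0.8 and mean
≥ 0.6, both inclusive; a gene is a predicted target when it carries ≥ 1
conserved site.

The nulls:

1. **TSS proximity** — one-sided KS test of |position| against
   Uniform(0, 2000); absolute distance is used since binding is expected
   symmetric around the TSS.
2. **Dinucleotide-preserving shuffle** — the Altschul–Erickson Euler-path
   method: exact preservation of all 16 dinucleotide counts and of the
   first and last base. Conservation scores are shuffled within base
   types, preserving each per-base-type score multiset exactly. Target
   prediction re-run on shuffled promoters gives the expected chance
   target count and an FDR (= expected/observed).
3. **DNase overlap** — observed number of genes whose sites overlap an
   open-chromatin interval by ≥ 1 base, against width-matched stretches
   drawn uniformly from promoter positions with G/C ≥ 0.79 (the G/C floor
   controls for open chromatin's G/C bias). The implementation enumerates
   all qualifying windows and samples among them, which is distributionally
   identical to the published acceptance-rejection procedure but cannot
   loop; promoters without any qualifying window are excluded with a
   warning.

# Tissue specificity

Per-gene focal-tissue z-scores (distance from the cross-tissue mean in
cross-tissue SD units; undefined for constant genes, which are dropped
pairwise). Species are aligned by shifting one species' scores so a
background gene set has exactly equal medians, then the foreground is
compared one-sided. Scale invariance (multiplying an atlas by a positive
constant) holds exactly.

# Enrichment

One-sided Fisher tests (hypergeometric tails, vectorized) per category
with ≥ 10 annotated universe genes, over the union of the disjoint test
and background sets restricted to annotated genes. Resampling FDR draws
test-size gene sets from the annotated background; per cutoff in
{0.05, 0.01, 0.005, 0.001} it reports median(resample count)/observed
count and the global p (fraction of resamples with at least the observed
count); the reporting cutoff is the largest grid value with FDR < 10% and
global p < 0.05. The count statistic is discrete, so the null global p is
conservative rather than exactly uniform — the tests check the size of the
test, not exact uniformity. A *single* isolated enriched category cannot
move the count statistic at the 0.05 cutoff (chance hits across ~20
categories dominate); with ancestor-propagated annotation — the form the
flat input tables are expected to arrive in — a true signal enriches its
ancestor chain and becomes globally visible, which is the world the
acceptance test builds.

# The synthetic generator: what it emulates, and what not

Expression is generated on a log-like additive scale: gene values are
Gaussian with SD `noise_sd` (default 1, in log2-expression units), batch
effects are additive gene-wise offsets (SD `noise_sd/2` by default),
planted group differences are mean shifts in pooled-SD units, and driver
targets follow `coupling·TF + √(1−coupling²)·noise`, giving a TF-target
correlation of c√v/√(c²v + 1 − c²) with v = 1 + d²/4 — the closed form the
recovery tests check against. Every TF carries a planted shift (so it
passes the effect-size gate), non-driver targets carry independent
random-signed shifts (providing eligible non-targets), and the same
regulon annotation is emitted for both cohorts. Defaults (2 × 6 samples,
d = 1.5, coupling 0.7, 30 targets for the driver) mirror the cohort sizes
and gate values of the motivating study design.

Deliberately *not* emulated: probe-level microarray structure,
mean-variance coupling of counts (a count mode exponentiates and
Poisson-samples when needed), phylogenetic sequence evolution in
promoters (backgrounds are i.i.d. at a stated G/C), and correlated
gene-gene noise. A green test on this world therefore establishes that
the statistics behave as designed under their own assumptions — not that
those assumptions hold for any particular real dataset.

Promoters span TSS ± 2,000 bp; planted sites carry the PWM consensus with
conservation Uniform(0.75, 1) (mean ≥ 0.6 by construction); background
conservation is Beta(1, 3) with 10% of bases unscored, so chance conserved
hits are rare but not impossible. DNase tracks cover planted sites (20 bp
padding) plus 150 bp background intervals to a stated coverage fraction
(default 6%). Paired tissue atlases default to 79 and 61 tissues.

# Numerical and policy choices

* Seeds: every stochastic routine takes a `seed` (NULL = ambient RNG);
  the pipeline expands one global seed into fixed per-stage offsets.
* Wilcoxon: exact for tie-free samples with both sizes ≤ 25, otherwise
  normal approximation with tie and continuity corrections.
* Fisher: one-sided hypergeometric tail; the reported odds ratio is the
  sample OR with an `Inf` sentinel for zero cells.
* Degenerate genes (zero variance in both groups, equal means) get
  p = 1, d = 0; zero pooled SD with unequal means gives d = NA with a
  warning.
* Medians use the midpoint convention for even n; background alignment in
  the specificity comparison is exact to the precision of the median.
* Coordinates: 1-based inclusive internally (R idiom); all exported site
  and interval positions are TSS-relative with downstream positive, and
  BED files use 0-based half-open promoter-local coordinates.

# Known limitations

* The regulatory-effect test conflates direct and indirect targets; it
  tests association of a regulon *as annotated*, not regulation of each
  member.
* Pooled-over-groups correlations mean a TF and target that respond in
  parallel to the group variable, without any regulatory link, can pass;
  the regulon permutation controls how often that happens by chance but
  cannot remove confounding shared group structure (see the CoC caveat).
* Batch-mean removal assumes additive, group-balanced batches.
* The MATCH operating point is a configurable convention, not a
  re-derivation of proprietary per-matrix thresholds.
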