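---
title: "Behavioral signature screening: models, statistics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral signature screening: models, statistics and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dbsa)
```

# The problem

High-content behavioral phenotyping platforms measure hundreds to
thousands of correlated features per animal. A disease model (for
example a Huntington's disease knock-in line) differs from wild-type
controls on a subset of these features — its *behavioral signature*.
If a library of reference compounds has been profiled on the same
platform in healthy animals, each drug's feature profile can be scored
*in silico* for its potential to push the disease-increased features
down and the disease-decreased features up. Drugs whose profiles run
opposite to the disease signature are candidates for symptomatic
treatment and repurposing, to be confirmed *in vivo*.

This package implements that screen end to end: signature extraction,
a two-tailed enrichment statistic with a permutation null, library
ranking with a cross-stratum consistency filter, and a decorrelated
feature analysis that quantifies phenotypic separation
(Discrimination Index) and treatment rescue (Recovery Index). A
synthetic cohort generator with planted ground truth makes every stage
testable without access to proprietary phenotyping data.

# Signature extraction

A cohort is a `BehaviorExperiment` (a `SummarizedExperiment` with one
numeric `features` assay, features × samples, and a mandatory `group`
column in `colData`). `featureTScores()` computes one unequal-variance
(Welch) two-sample t statistic per feature, case minus control in the
numerator. Welch rather than pooled-variance t is the safe default for
the small, unequal group sizes typical of animal cohorts; whether a
moderated statistic would behave better at very small n is an open
question we deliberately did not pursue, since the downstream
enrichment statistic only consumes ranks and signs.

Two degenerate situations are handled without exceptions, because large
behavioral batteries routinely contain them:

* features constant in both groups (zero pooled standard error) get
  t = 0 and a `zeroVariance` flag — they can never enter a signature;
* missing cells are resolved *before* construction by a configurable
  policy (`drop-feature` by default, `drop-sample`, or
  `impute-group-mean`).

`buildDiseaseSignature()` selects up to `kPerTail` features per
direction subject to `|t| >= minAbsT`, ordered by |t| descending. The
defaults (`kPerTail = 20`, `minAbsT = 0`) reflect the tens of features
such signatures typically carry; both knobs are exposed because rank
cutoffs and t thresholds are equally defensible selection rules.

# The two-set enrichment statistic

Each library drug-dose is a `DrugRanking`: features ordered by the
drug-vs-vehicle t score, descending, with ties keeping the stable
input order (the statistic depends on rank order, so the tie-break is
part of the contract). Walking the ranking from top to bottom, a
signature member ("hit") at rank $i$ increments a running sum by
$|s_i|^w / \sum_{hits} |s|^w$ and a non-member decrements it by
$1/(n - m)$, where $m$ is the set size and $w$ the weight exponent
(default 1; $w = 0$ gives the classic equal-step Kolmogorov–Smirnov
form). Both the hit and the miss mass integrate to one, so the curve
always ends at zero — a conservation property every curve is tested
for. The enrichment score (ES) of a set is the signed extremum of its
curve; when the positive peak and the negative trough tie in magnitude
(common at $w = 0$) the positive extremum is taken, with a small
tolerance so that the choice is stable against last-bit differences in
summation order.

The *theoretical maximum* curve reported alongside is the walk the set
would trace if its members occupied the top $m$ ranks with their own
weights — an upper envelope useful for plotting, since the statistic
itself is scale-free.

Both signature sets are evaluated on the same ranking in a single
pass and combined into a reversal score:

$$\mathrm{reversal} = \frac{ES_{decreased} - ES_{increased}}{2},$$

which is $+1$ for a perfect reverser (disease-increased features at
the bottom of the drug ranking, disease-decreased at the top) and $-1$
for a perfect mimic. When the two extrema share a sign — both sets
piling on the same end of the profile — the combined score is set to
zero, following the convention of connectivity-style reversal scoring:
co-enrichment in one direction is not reversal. The rule is exposed as
`sameSignZero` because it is a convention, not a theorem; one place it
must be off is p-value calibration (below).

## Permutation null and multiple testing

Significance is non-parametric: signature *membership* is permuted
over the ranked features — disjoint random increased/decreased sets of
the observed sizes, drawn uniformly without replacement — while the
drug ranking stays fixed, and the reversal score is recomputed per
draw. Permuting membership rather than animals keeps the library
screen independent of per-drug sample data, which a screening lab may
not retain. The add-one estimator
$p = (1 + \#\{perm \ge obs\})/(B + 1)$ is one-sided toward reversal
and never smaller than $1/(B+1)$; $B = 1000$ by default, and every
stochastic step requires an explicit seed.

On six-feature rankings with singleton sets the Monte-Carlo p is
checked against exhaustive enumeration of all 30 disjoint ordered set
pairs; with random null signatures the p distribution is checked for
uniformity by a Kolmogorov–Smirnov test. The calibration check runs
with `sameSignZero = FALSE`: the same-sign rule places a point mass of
the null at zero, and no valid p-value on a statistic with an atom can
be uniform — the rule trades calibrated p-values near zero for
protection against co-enrichment artifacts, which is the right trade
in a screen ranked by score.

`screenLibrary()` attaches Benjamini–Hochberg q-values within each
stratum but ranks by reversal score (p-value, then lexicographic drug
id, as tie-breaks): the screen is a hypothesis generator, and the
published practice it follows ranks without a formal correction while
still reporting q. `consistencyFilter()` then applies intersection
semantics across strata (for instance both sexes): a pair is kept only
if its reversal score is positive and its p (or q) passes `alpha` in
*every* stratum — a deliberate false-positive control that trades
sensitivity for reproducibility.

# Decorrelated feature analysis

`fitDRFSpace()` standardizes each feature on the pooled samples of the
two reference groups and eigendecomposes the pooled covariance of the
standardized data. Components with eigenvalues below $10^{-10}$ of the
largest are dropped (rank deficiency), then the smallest set of
components reaching `varianceKept` (default 0.95) is retained and
re-ranked by absolute between-group Welch t on the component scores,
so component 1 is the most discriminant direction. The rotation has
orthonormal columns and the transformed pooled data has diagonal
covariance by construction. Projections are whitened by default — each
component scaled to unit pooled-training variance — which places all
downstream geometry in the pooled Mahalanobis metric.

## Discrimination Index

The index is the mean held-out accuracy of a nearest-centroid linear
classifier over repeated stratified random splits (default 200
subsamples, half of each group held out), expressed on the 50–100
scale and clamped below at 50. Within each split the components are
additionally standardized by the *training* samples' within-class
pooled SD, making the rule a diagonal LDA. Two details matter:

* the within-class metric must come from the training split only.
  Baking within-class scaling into the space itself uses the held-out
  samples' labels and inflates the null index by several points; with
  the per-split metric, exchangeable groups average 50–52 over
  replicates, as they should.
* the index is clamped at 50 rather than folded, so an observed 50
  can never be significant — the label-permutation p
  (`discriminationPValue()`, add-one estimator over full index
  recomputations) is 1 by construction there. The decorrelating
  rotation is label-free, so it is reused across label permutations.

## Recovery Index

Every sample of the model, wild-type and test (treated) groups is
projected into whitened DRF space and then orthogonally onto the
segment joining the model and WT group means, with the scalar
coordinate scaled so the model mean is exactly 0 and the WT mean
exactly 1. Recovery is 100 × the test group's mean coordinate,
clamped to [0, 100]. The mean of per-sample coordinates equals the
coordinate of the mean under an orthogonal projection; we compute the
former, and report the per-sample coordinates for plotting and for the
significance test: a one-sided Welch t comparing test vs model
projections, the alternative being a shift toward the wild-type end
(the direction "rescue" implies).

Because the whitened projection is the pooled Mahalanobis geometry,
the recovery coordinate is invariant under any invertible affine map
of the raw features when the space is refitted with
`varianceKept = 1` (full rank); with the default 0.95 the invariance
is approximate, since truncation can select slightly different
subspaces on either side of the map. Degenerate inputs fail loudly:
coincident model and WT means leave the axis undefined and raise an
error rather than returning a clamped value.

# The synthetic cohort generator

`simulateTruth()` / `simulateCohort()` / `simulateLibrary()` emulate
the *shape* of platform data, not its distributions. Features follow a
correlated Gaussian model: $q$ shared latent factors with loadings of
variance `factorStrength`/q per feature, plus independent noise of SD
`noiseSd`, giving each feature a total SD of
$\sqrt{factorStrength + noiseSd^2}$. The disease adds a signed effect
of `effectSize` total-SD units on `nAffected` randomly chosen
features; sign-flipped effects stand in for latency-like features that
move opposite to their underlying behavior. Library drugs are planted
archetypes — an exact reverser ($-s\times$ the disease effect), a
mimic ($+s\times$), partial reversers (full reversal on a random
fraction of the affected set) and nulls — with dose scaling the effect
proportionally, and all drug-dose groups contrasted against one shared
vehicle group, mirroring a single-vehicle screening design.

Defaults (200 features, 40 affected at 1.5 SD, 5 factors of strength
0.6 against unit noise, 15 animals per group, a 50-drug two-dose
library) describe a mid-sized phenotyping study: group sizes of 10–15
are the norm in behavioral pharmacology, and an aggregate effect of
1–2 SD spread over a fifth of the features produces the
70–90% discrimination range reported for established disease models at
symptomatic ages.

What the generator deliberately does **not** emulate: mixed-scale
count/latency/probability features, floor and ceiling effects,
heavy-tailed or zero-inflated distributions, batch and litter effects,
and dose–response nonlinearity. Passing tests therefore demonstrate
that the statistics behave correctly under a known correlated Gaussian
truth — rank recovery, calibration, exactness — not that real
platform data meet these assumptions; on real data the Welch t's
robustness and the rank-based enrichment carry most of the load.

# Numerical choices and determinism

* Seeds are mandatory for every stochastic operation; child streams
  are derived from the top-level seed by a fixed integer recurrence,
  so a pipeline run (`runPipeline()`) is byte-reproducible — the
  test suite reruns a full simulated screen and compares output files
  verbatim.
* Eigenvalues below $10^{-10}$ of the largest are treated as zero;
  zero-variance features get unit scale (and zero contribution) during
  standardization.
* Enrichment extremum ties resolve to the positive peak (tolerance
  $10^{-9}$); drug-ranking score ties keep input order.
* The test suite exercises the prescribed property sizes — 200 random
  oracle instances, 10,000-draw vs exhaustive permutation comparison,
  1,000-replicate calibration, 100-seed planted-reverser power, 200
  null replicates for discrimination calibration — with cohort sizes
  (tens of features, 10–15 per group) chosen to keep a full run around
  a minute while leaving Monte-Carlo margins wide.

# Known limitations

* The enrichment statistic consumes a single ranking per drug-dose;
  dose–response structure is ignored by design (doses are screened as
  independent rows).
* Permutation of signature membership tests the null of "a random
  feature set of this size", not "no drug effect"; the two coincide
  for screening purposes but differ if per-drug sample data were
  available for animal-level permutation.
* The decorrelation is a linear, second-moment construction; strongly
  non-Gaussian feature distributions can leave dependence the rotation
  does not remove.
* With `varianceKept < 1`, recovery's affine invariance and the
  discrimination index are subject to truncation choices; analyses
  that need exact invariance should fit with `varianceKept = 1`.
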