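---
title: "Morphometric similarity networks, spatial nulls and transcriptomic association: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric similarity networks, spatial nulls and transcriptomic association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msntools)
```

## The analysis in one paragraph

`msntools` implements a case–control analysis of cortical anatomy built on
morphometric similarity networks (MSNs). Each subject contributes seven
regional morphometric features (cortical thickness, surface area, mean and
Gaussian curvature, folding and curvature indices, grey-matter volume) over a
308-region cortical parcellation. Per subject, features are z-scored across
regions and every pair of regions is correlated across the seven features,
giving a 308 × 308 similarity matrix; a region's *MS strength* is the signed
sum of its correlations to all other regions. Group differences in regional
strength are assessed by per-region linear models with demographic
covariates and Benjamini–Hochberg FDR control; spatial correspondences
between cortical maps are tested against spin-rotation null models that
preserve spatial autocorrelation; and the left-hemisphere contrast map is
related to a panel of gene-expression maps by rank-1 partial least squares
with permutation and bootstrap inference. A synthetic-cohort generator with
planted ground truth makes every stage testable end to end.

## Morphometric similarity

For subject $s$, let $x_{rf}$ be feature $f$ at region $r$. Features are
z-scored across regions *within subject* ($\tilde{x}_{\cdot f}$ has mean 0,
SD 1), removing inter-feature scale differences. The MSN entry is
$M_{ij} = \mathrm{cor}(\tilde{x}_{i\cdot}, \tilde{x}_{j\cdot})$ over the 7
features (Pearson by default; a Spearman variant ranks the 7 features within
each region). Regional strength is $S_r = \sum_{q \ne r} M_{rq}$ — the
*signed* sum, since negative strength (regions architectonically
differentiated from the rest of cortex) is meaningful. The diagonal is
stored as 0 and excluded from strength: a constant self-similarity would
shift all strengths equally and cancel in any group contrast.

Whether z-scoring should be per subject or pooled across the cohort is
genuinely open; per subject is implemented because it keeps each subject's
network a function of that subject's anatomy alone, and the group contrast
then compares networks rather than cohort-referenced scores.

## Group statistics

Each region's strength is regressed on group, age, sex and age × sex (OLS;
age mean-centred before the interaction is formed, for conditioning — the
group contrast is unchanged). The group coefficient's two-tailed Wald t and
p are reported with BH-FDR across the 308 regions. Total intracranial
volume can be added as a nuisance regressor (the replication variant), and a
cortical-thickness response additionally adjusts for the subject's mean
cross-hemispheric thickness. Degenerate, perfectly separated regions yield a
capped |t| of 10^6 with a warning rather than NaN. The global comparison is
a Welch t-test on subject-mean strength (group variances are not assumed
equal) plus a two-sample Kolmogorov–Smirnov test on the two groups'
mean regional strength distributions. Network-level contrasts average each
subject's strength within each Yeo-7 or von Economo label *first*, then fit
the same linear model per label with FDR across the 7 labels; this
aggregate-then-fit composition is the simplest one consistent with
reporting network-level FDR p-values, and it is recorded here as an
assumption. FDR families are kept separate by design: 308 regions, 7 labels
per atlas, 3 attendance sets.

## Spin-permutation nulls

Correlations between cortical maps are tested against nulls that preserve
spatial autocorrelation: random rotations of each hemisphere's spherical
geometry (the right hemisphere uses the x-mirrored rotation, so hemispheres
rotate as mirror images and no permutation crosses the midline). Rotations
are drawn uniformly on SO(3) by QR orthonormalisation of Gaussian matrices
with determinant forced to +1. This package operates at *parcel-centroid*
level — it consumes parcel tables, not vertex meshes — so after rotation
each region is reassigned to the nearest original centroid, greedily in
order of increasing great-circle distance with each centroid used once,
which guarantees a bijection. `p_spin` counts null |r| values at or above
the observed |r| with +1 smoothing, so it is never 0 and never below
1/(n_spins + 1); a one-sided mode is provided since the two-sided rule on
|r| is a choice (the alternative reading, "greater", is exposed).

Parcel-level reassignment slightly scrambles a map's autocorrelation at
assignment collisions. In our calibration experiments the test holds its
nominal 5% level on whole-cortex smooth map pairs, while single-hemisphere
supports with very smooth maps (length scale comparable to the hemisphere)
can run mildly liberal (~6–8% empirically) — a known cost of parcel-level
spins worth remembering when p_spin is near threshold.

## Rank-1 PLS with permutation and bootstrap inference

With gene maps $X$ (columns z-scored across regions) and the centred
left-hemisphere t-map $y$, the first PLS component for a univariate
response has a closed form: weights $w \propto X^\top y$ (the dominant
singular direction of the cross-covariance), scores $Xw$, and the variance
explained is the squared correlation of scores with $y$. Only this first
component is used, so the closed form replaces a general multi-component
algorithm and is checked in the tests against an independent SVD oracle.
The variance-explained estimator (squared score–response correlation,
equivalently the R² of the rank-1 regression) is a documented assumption —
other conventions exist. Weights are oriented so that the score–response
correlation is non-negative; flipping the sign of $y$ flips weights and
scores exactly and swaps the positive and negative gene sets.

Significance of the variance explained comes from permuting the response's
region labels (the only exchangeable null available on one map); the
spatial correspondence of PLS1 scores with the t-map is additionally
anchored by a left-hemisphere spin test. Gene contributions are ranked by
bootstrap Z: regions are resampled with replacement, PLS1 is refitted
(columns re-centred), each bootstrap weight vector is sign-aligned to the
original, and Z is the original weight over the bootstrap SD. Genes pass at
the two-tailed 99% threshold on |Z| and are additionally screened by BH-FDR
across genes; both stages' survivors are reported separately so either
convention can be read off.

One caveat the tests document: under a *fully null* response the
sign-alignment step truncates the bootstrap distribution (bootstrap weight
vectors are near-orthogonal to the original, so flips are frequent) and
inflates |Z| — about 8% of null genes pass the 99% threshold instead of 1%.
With a genuine association present, which is the regime the ranking is used
in, alignment is stable and unassociated genes are calibrated (~1.7% with
6 of 66 genes planted at association 0.7). The permutation test on the
variance explained, not the bootstrap, is the significance gate for the
component itself.

## The synthetic cohort generator

The generator produces parcel-level tables only — no surfaces, no voxels —
with the statistical structure the analysis relies on and known ground
truth. Its defaults are the study conditions used throughout the tests.

**Parcellation.** Region centroids are quasi-uniform on each hemisphere's
unit sphere (Fibonacci lattice under a random rotation); Yeo-7 and von
Economo labels are spatially contiguous k-means patches, so label maps are
autocorrelated as in real atlases.

**Morphometry.** Every subject shares a smooth regional profile: a
principal morphometric gradient (Gaussian random field over the centroids,
exponential kernel, length scale 0.4 rad) carried by fixed inter-feature
loadings — thickness, area, volume and folding positive, the curvature
measures negative — plus smaller feature-specific smooth structure and
independent subject noise. Two properties of the gradient matter. First,
the loadings have equal magnitude, so all features carry the same variance
and the per-subject z-scoring acts uniformly across features — otherwise a
planted variance perturbation would leak into every region's standardized
values as a group-coherent distortion. Second, the gradient field passes
through a lognormal transform (skew 0.7): a minority pole of deep gradient
values against a shallow majority, mimicking how primary cortices stand out
against the broader association cortex. Without the skew, the two poles of
a centred Gaussian field balance by construction and the existence of
strong strength hubs varies wildly from realisation to realisation; with
it, hub strengths are stable, which the planted-effect machinery needs.
Defaults: gradient SD 2, feature-specific SD 0.6, subject noise SD 0.6 —
chosen so pairwise regional correlations span the strong positive and
negative values seen in real MSNs while between-subject strength
variability remains substantial.

**Planted group effects act on feature covariance, not means.** MS is a
correlation statistic: a mean shift is removed by z-scoring and would plant
nothing. Where the effect map is negative, user-group subjects receive
extra independent feature noise at that region, decorrelating it from the
rest of cortex; where positive, the subject's deviation from the shared
profile is shrunk toward it (homogenisation). The decorrelating noise is
scaled by the region's own centred-profile SD so the induced correlation
attenuation is identical at every planted region — with a fixed noise SD,
deep-pole and shallow-pole regions attenuate differently and the imbalance
shows up as a spurious group difference across the whole cortex.

**Where effects are planted matters.** A covariance perturbation changes
$S_r$ in proportion to the region's baseline strength, so effects planted
at weakly connected regions are invisible at any effect size. The
`hub_effect_map()` planner therefore selects hubs — half from each strength
pole of a reference null cohort — and refines the set by greedy swaps so
that its summed correlation to the rest of cortex is as near zero as
possible. That last step bounds the *spillover*: decorrelating a region
perturbs every other region's strength through their shared edges, and if
the planted set's correlation columns do not cancel, the perturbation is
coherent across users and floods the contrast map with false positives.
This is a real property of sum-of-correlation statistics, not an artifact:
localised anatomical change genuinely moves the strength of connected
regions. At the frozen defaults (20 hubs, effect scale 1.5), a pilot of 25
cohorts gave sensitivity 1.00 at FDR 0.05 with a false-positive rate of
0.003; the effect scale was fixed from that pre-registered sweep before the
acceptance tests were written and not revisited.

**Expression.** Gene maps live on the left hemisphere only (as
AHBA-derived maps do). Unplanted genes are independent smooth fields
(default length scale 0.5 rad), z-scored across regions. Planted genes mix
the z-scored *association target* with smooth noise at a chosen association
strength (0.7 in the study configuration). The target is not the effect map
itself: the effect map's sign encodes the planted *mechanism*
(decorrelate vs homogenise), whereas the direction of the induced group
contrast at a hub is opposite to its baseline strength — decorrelating a
negative-strength hub *raises* its strength. `hub_effect_map()` therefore
also returns the expected-contrast map (−mean strength at planted hubs),
and that is what planted genes correlate with.

**Covariates** follow the study design the generator emulates: two groups
of 24, ages ~55 with the two groups' means and SDs matched to the cohorts'
reported demographics, sex balanced, ceremony attendance log-normal with
mean ≈ 563 and SD ≈ 650 (users only), and optional TIV tracking total
grey-matter volume at correlation ≈ 0.8. Feature values are returned in
physical units (mm, mm², mm³, index units) so the z-scoring step is
exercised, not bypassed.

**What the generator does not emulate:** real effect topographies (no
posterior-cingulate or insula geography), scanner or protocol differences
between cohorts, inter-feature correlations beyond the single gradient,
hemispheric asymmetries, or AHBA donor sparsity. Passing tests demonstrate
that the machinery recovers what it claims under the generator's
assumptions — they do not certify sensitivity or specificity on real MRI.

## Reproducibility and numerical conventions

Every stochastic stage takes an explicit integer seed, and all draws flow
through one seeded generator per call with no global state left behind.
The pipeline derives per-stage seeds by hashing the stage name into the
master seed, so adding a stage never perturbs another stage's stream; fixed
seeds reproduce byte-identical output tables. Other conventions: BH
adjustment via `p.adjust`; Welch correction for the global t-test;
Spearman ties broken by average rank; spin p never 0 by +1 smoothing;
zero-variance features, regions, maps and responses are errors that name
the offender rather than silent NaNs; a response orthogonal to every gene
map yields the zero fit with a warning.

## Problem sizes used in the validation suite

The acceptance tests run at the study conditions — 24 + 24 subjects, 308
regions (152 left), 66 genes — with 200 null cohorts for calibration, 500
map pairs × 1,000 spins for the autocorrelation-robustness check, and 100
cohorts × 1,000 permutations/bootstraps for parameter recovery. The
analysis scripts use 10,000 spins/permutations/bootstraps, matching the
resampling depth of the original analysis; the demo configuration defaults
to 1,000 so a full run completes in seconds.
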