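---
title: "Sub-volume radiomics and survival risk modelling with rimcore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sub-volume radiomics and survival risk modelling with rimcore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rimcore)
```

## The scientific problem

Radiomic risk models usually summarise the entire gross tumour volume
(GTV) of a delineated lesion. Tumours, however, are spatially organised:
proliferating, well-vascularised tissue concentrates at the periphery while
hypoxic or necrotic tissue accumulates in the centre, and these regional
differences plausibly carry different prognostic information. `rimcore`
implements the full analysis needed to ask whether the *rim* of a tumour is
more prognostic than its *core* for a time-to-event endpoint such as
loco-regional control after radio-chemotherapy:

1. **Sub-volume geometry** — split a binary tumour mask on a 1 mm isotropic
   grid into a peripheral rim and a complementary core by an inward
   Euclidean margin (3 or 5 mm), optionally extend the rim outward into
   surrounding tissue (1/2/3/5 mm), and re-segment ROIs to the soft-tissue
   window of −150 to 180 HU.
2. **Feature extraction** — 1538 features per ROI: 18 intensity statistics,
   38 histogram features and 95 texture features on the base image and on
   nine filtered companions (eight stationary coiflet-1 wavelet
   combinations and one multi-scale Laplacian-of-Gaussian image), plus 28
   morphological features on the base image.
3. **Risk modelling** — five bootstrap feature-selection methods crossed
   with six survival learners, trained as ensembles over bootstrap
   resamples of an exploratory cohort, with risks averaged into a single
   score per patient.
4. **Evaluation** — Harrell's concordance index with percentile-bootstrap
   confidence intervals, median-risk Kaplan–Meier stratification with
   log-rank tests, a 20 cm³ tumour-volume subgroup analysis, and a paired
   sign-flip comparison of sub-volumes across model combinations.
5. **Synthetic cohorts** — because clinical planning CTs cannot be
   redistributed, a phantom generator produces cohorts with a *known*
   rim-localised prognostic signal, so every stage of the pipeline is
   testable end to end.

## The phantom generator

`generate_phantom()` builds an ellipsoidal tumour (semi-axes in mm) on a
CT-like background (−50 HU, global Gaussian noise of 5 HU). Inside the
mask, voxels below a normalised radius of 0.85 form a homogeneous core at
40 HU; the remaining shell is the textured rim at a mean of 60 HU whose
voxelwise noise SD is

```
sd(z) = max(0, 20 * (1 + 0.5 z)),
```

a linear map of a per-patient latent signal `z ~ N(0, 1)` floored at zero.
Texture heterogeneity — not volume — therefore carries the prognosis.
Tumour intensities are clamped to \[−150, 180\] HU so that HU
re-segmentation never erodes a clean phantom.

Outcomes follow a proportional-hazards Weibull model: event times
`T ~ Weibull(shape = 1.2, scale = 50 * exp(-beta * z / shape))` months, so
the hazard is multiplied by `exp(beta * z)`; censoring is
administrative-uniform on `(0, 60)` months. These defaults give event
fractions near 40%, matching what locally advanced head-and-neck cohorts
report for loco-regional recurrence. `generate_cohort()` draws volumes
log-uniformly over 5–150 cm³ (spanning the 20 cm³ subgroup threshold,
which corresponds to a spherical radius of roughly 1.5 cm), perturbs the
axes anisotropically at fixed volume, and splits patients 2:1 into
exploratory and validation cohorts.

**Where the texture boundary sits, and why.** The minimum-core rule (below)
guarantees that the geometric core always reaches at least
`0.40^(1/3) = 0.737` of the normalised radius. If the phantom's constant
core ended at 0.6, roughly half of every geometric core would lie inside
the textured shell and core features would inherit nearly all of the
latent signal — the rim-versus-core contrast the package exists to measure
would be erased by construction. The boundary therefore sits at 0.85
normalised radius: geometric cores stay signal-free for tumour radii up to
about 33 mm, while the geometric rim remains roughly two-thirds textured.

What the phantoms deliberately do *not* emulate: scanner reconstruction
kernels, contrast phases, multi-centre acquisition variation, infiltrative
(non-ellipsoidal) tumour shapes, or spatially heterogeneous necrosis.
Passing tests on phantoms demonstrate that the pipeline recovers a known
regional signal; they do not certify clinical performance.

## Sub-volume geometry

Margins are defined on the exact Euclidean distance transform
(voxel-centre metric): a voxel belongs to the candidate core when its
distance to the nearest background voxel is at least the margin
(inclusive). The rim is the set difference, so rim and core always
partition the mask. When the candidate core holds less than 40% of the
tumour, the margin is relaxed to the largest distance threshold whose
super-level set reaches the floor, ties included — a deterministic,
order-free rule that reproduces the floor exactly. Outward extensions
dilate the mask by the same metric and subtract the core; extensions that
reach the grid boundary are truncated with a warning.

At 1 mm voxels the digital geometry is accurate to about half a voxel in
radius, which for shells a few millimetres thick translates into
voxel-count deviations of 5–20% from continuum shell volumes; tests
therefore check radius-equivalent agreement (within 0.5 mm) and exact
equality against a brute-force all-pairs distance scan.

Images are resampled to isotropic grids with separable natural cubic
splines (masks trilinearly, thresholded at 0.5); natural splines reproduce
affine intensity fields exactly, which the tests exploit.

## The filter bank

The stationary (undecimated) coiflet-1 decomposition applies the 6-tap
low- or high-pass analysis filter along each axis, giving the eight
`{L,H}³` combinations on the input grid with symmetric boundary padding.
The Laplacian-of-Gaussian image combines scale-normalised responses
(`sigma² ∇²G_sigma`) at kernel widths of 1, 2, 3, 5 and 6 mm into one
image by their voxelwise mean — the combination rule for collapsing five
widths into a single image is not uniquely determined by convention, and
the mean is symmetric and scale-balanced; `log_filter(combine = "stack")`
exposes the per-scale responses for anyone preferring another rule.
Discrete second-derivative kernels are DC-corrected so constants map to
exactly zero. Filtering always runs on the full grid before masking, and
the ROI applied to every filtered image is the *base-image* re-segmentation
— HU thresholds are meaningless on filter responses.

## Feature definitions and numerical choices

Discretisation uses a fixed bin number (32) over the in-ROI intensity
range for all discretised families on all transforms. Fixed bin *size* is
ill-defined on wavelet/LoG responses, whose units are no longer HU, and a
fixed bin number makes discretised features invariant to intensity shifts
(a property the tests assert).

Texture families follow the standard grey-level matrix definitions: GLCM
(25 features) and GLRLM (16) are accumulated per 13 unique 3D directions
at distance 1 and averaged over directions after feature computation; zone
and distance-zone families (GLSZM/GLDZM, 16 each) use 26-connected zones,
with the distance map counting city-block steps to the ROI border; NGTDM
(5) and NGLDM (17, dependence threshold 0, 26-neighbourhood, dependence
count offset by one) complete the 95. Degenerate inputs (single-voxel
ROIs, constant ROIs, zero variances) map to documented constants — never
silent `NA`s — and each fallback leaves a record in `rimcore_log()`.

Morphology (28 features) is computed on the geometric, non-re-segmented
mask: its surface comes from a marching-tetrahedra iso-surface of the
binary mask with five Laplacian smoothing passes (lambda 0.5). Smoothing
removes the half-voxel staircase that would otherwise inflate the area of
oblique surfaces by ~25%; the cost is mild rounding at sharp edges (a 10
mm cube's surface reads ~10% low), the right trade-off for blob-like
tumours. Mesh volume, area, sphericity and their derivatives come from
that mesh; the maximum 3D diameter and the convex-hull densities come from
an exact incremental 3D hull of the surface voxel extremes expanded by
half-voxel face offsets; the oriented bounding box is PCA-aligned (an
approximation to the minimal box) and the minimum-volume enclosing
ellipsoid is fitted with Khachiyan's algorithm on the hull vertices. The
28-item list is the full standard morphology family minus the enclosing
ellipsoid's *area* density, which would stack an area approximation on an
already approximate ellipsoid. Moran's I and Geary's C use a
deterministic even-stride subsample above 1000 voxels. Intensity-weighted
members (integrated intensity, centre-of-mass shift, Moran, Geary) use the
re-segmented intensities.

The expanded per-ROI contract is `(18 + 38 + 95) × 10 + 28 = 1538`
columns, ordered by `feature_manifest()`.

## Risk modelling

`preprocess_features()` z-scores every feature with exploratory-cohort
statistics only, drops zero-variance features, clusters features by
complete-linkage on `1 − |Spearman correlation|` (cut so every cluster
pair correlates at |rho| ≥ 0.9), and replaces clusters by the mean of
their member z-scores — one meta-feature per cluster. Validation rows are
always transformed with the exploratory statistics and cluster map; no
quantity derived downstream (rankings, hyper-parameters, the median-risk
cutoff) sees validation outcomes, and a dedicated audit test shuffles
validation outcomes to prove it.

Feature selection runs on bootstrap resamples (1000 by default; desk-scale
runs use 25–50) and aggregates per-bootstrap rankings by mean rank, ties
broken by name. The five selectors: absolute Spearman correlation with
event time among event patients; mutual information of the 4-bin
equal-frequency-binned feature with the event indicator (MIM); greedy
forward MI with summed-redundancy penalty beta = 1 (MIFS); greedy forward
MI with mean-redundancy penalty (MRMR); and permutation importance from a
random survival forest (RFVI). The Spearman target (time among events) and
the greedy tail rule (unordered features share a tail rank) are package
choices where convention is silent.

The six learners share one contract — risk scores oriented so higher means
earlier recurrence: Cox partial likelihood (`survival::coxph`);
componentwise-linear gradient boosting of the Cox partial likelihood
(implemented in the package, Breslow ties, step 0.1); gradient-boosted
trees on the Cox loss and on the Weibull accelerated-failure-time
likelihood (xgboost; the AFT risk is the negated predicted log event
time); and two survival forests (ranger) split by log-rank and by
maximally selected rank statistics, with risk the summed cumulative
hazard. Hyper-parameters come from a seeded random search (signature size
k in 1..10 plus per-learner grids) scored by mean out-of-bag concordance
over bootstrap fits. Ensembles average the risk scores of the bootstrap
fits; fits that fail (all-censored resamples, non-convergence) are dropped
with a log record, and training aborts only if more than half fail.

The representative combination for a sub-volume pairs the selector whose
median validation C-index over learners sits closest to the median of
selector medians with the learner chosen analogously (ties
lexicographic).

## Evaluation

Harrell's C (via `survival::concordance`, tied risks credited one half,
Harrell comparability under censoring) is checked against brute-force pair
enumeration up to n = 20. Confidence intervals are percentile bootstrap
over patients. Stratification uses the exploratory median risk, applied
unchanged to validation (ties go to the low-risk group). Kaplan–Meier and
log-rank come from the survival package. The sub-volume comparison across
model combinations is a paired sign-flip permutation test on per-combo
C-index differences (10,000 seeded draws, exhaustive when feasible,
two-sided) — a deliberately assumption-light replacement for multi-level
modelling of the combination grid, testing the same null of no sub-volume
effect.

## Desk-scale study sizes

The replicate study that checks the headline direction — rim-based models
outperforming core-based models — runs 20 seeded replicates of n = 300
cohorts (2:1 split), beta = 2, ensembles of B = 50 bootstrap Cox fits on
Spearman-selected (B = 25) base-image intensity statistics, with tumour
volumes spanning 5–40 cm³. Base-image statistics are where the generator
places its signal (rim noise SD); the filter bank, texture and morphology
families are exercised by their own oracle and contract tests. At these
sizes the whole study completes in minutes on one CPU; the observed gap
(rim minus core validation C-index ≈ 0.3) makes the ≥ 0.05-in-80%-of-seeds
criterion comfortable rather than marginal. Null-calibration runs the
same pipeline at beta = 0 across all thirty selector-learner combinations
and expects chance-level validation concordance.

## Known limitations

* Phantoms are ellipsoids with radially organised texture; none of the
  morphological features beyond size/shape sanity can be validated against
  clinical ground truth here.
* Mesh-based surface areas are biased low at sharp edges (see above);
  voxel-count volumes are exact by construction.
* The texture feature formulas follow the standard grey-level matrix
  definitions, but no reference-phantom certification against an external
  implementation is bundled.
* The multi-scale LoG combiner (voxelwise mean) and the exact membership
  of the histogram and morphology families are frozen conventions,
  documented in `feature_manifest()`; counts, not memberships, are the
  tested contract.
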