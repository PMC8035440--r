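---
title: "Functional connectivity density mapping: models, parameters, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional connectivity density mapping: models, parameters, and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(fcdensity)
```

# The measure

Binarized functional connectivity density (FCD) treats each gray-matter
voxel of a resting-state BOLD run as a node in a graph whose edges are
pairwise Pearson correlations exceeding a threshold (`r_threshold`, default
0.3, strict inequality). The degree of a voxel is split by Euclidean world
distance at a sphere radius (`radius_mm`, default 6 mm, the boundary pair
counted as local): connections inside the sphere form the *local* FCD
(lFCD), connections beyond it the *long-range* FCD (longFCD). Note that
this is the fixed-sphere definition of local FCD, not the older
region-growing one; only voxels inside the gray-matter mask participate,
self-correlation is excluded, and a zero-variance series contributes no
edges but stays in the mask with degree zero.

Per subject the two raw count maps are divided by their own within-mask
mean, converted to Z scores over the mask (population SD, i.e. divide by
N), and smoothed with a Gaussian kernel of 6 mm full width at half maximum
(sigma = FWHM / (2 * sqrt(2 * log 2)) per axis, in voxel units). Smoothing
is mask-renormalized — map-times-mask and mask are convolved separately and
divided — so in-mask values are not diluted toward zero at the mask edge.
The smoothed, normalized maps are what enter group statistics.

Two implementations of the degree computation coexist deliberately:
`compute_fcd()` streams correlations in voxel blocks and never materializes
the full matrix, while `brute_force_fcd()` builds the complete correlation
and distance matrices. Exact integer agreement between the two on random
instances is a standing test contract, as are conservation
(lFCD + longFCD = global degree), monotonicity in threshold and radius, and
covariance under grid isometries.

# Preprocessing chain

The temporal chain runs in a fixed order per subject:

1. drop the first `n_drop = 10` volumes (signal equilibration);
2. exclude the subject entirely if any retained translation exceeds 1.5 mm
   or any rotation exceeds 1.5 degrees — strictly "more than", so a subject
   peaking at exactly 1.5 mm is retained;
3. regress out, with an intercept, the Friston-24 motion expansion (6
   rigid-body parameters, their one-lag copies zero-padded at the first
   row, and the squares of both sets) plus the whole-brain, white-matter
   and CSF mean signals and their first-difference derivatives (30 columns
   total; linearly dependent columns are dropped with a warning);
4. linearly detrend and bandpass to 0.01–0.1 Hz.

The filter is a zero-phase frequency-domain band window with a raised-cosine
taper one frequency bin wide at each edge: no phase distortion of
correlations, at least 90% amplitude retention for tones inside the band,
at most 10% for tones well outside, and near-idempotence (a second pass
changes in-band amplitude by under 1%). Because the whole
detrend-plus-filter chain is linear in time it is applied as a single
precomputed t-by-t operator; the operator path is exactly equal (to
rounding) to applying the steps one by one, which the tests verify.
Regression and filtering are restricted to in-brain voxels; outside-brain
voxels are zeroed.

"Global signal" is defined as the mean over the whole-brain mask. The
intercept in every regression makes residual means exactly zero, which
simplifies the later correlation step.

# Group statistics and cluster-extent correction

Within each group a one-sample t-map (sample SD, df = n − 1) and between
groups a pooled-variance two-sample t-map (df = nA + nB − 2) are computed
voxel-wise on the smoothed maps; zero-variance voxels are set to t = 0 and
flagged. Voxels are thresholded two-tailed at p < .01 using the t
distribution with the map's df; connected components (26-connectivity by
default; 6 and 18 available) are formed separately for positive and
negative voxels, and only components at least as large as a Monte-Carlo
cluster-extent threshold survive, targeting a family-wise cluster-level
p < .05. Peak coordinates are reported at the maximum-|t| member voxel
(ties broken by lowest linear index) mapped through the affine; anatomical
labelling is out of scope — tables carry world coordinates only.

Two design choices here deserve their own account, because both were made
against the simplest reading of the correction and both are driven by
measured calibration:

**Smoothness entering the null.** The classic shortcut is to simulate null
noise at the smoothing kernel's FWHM (6 mm). For FCD maps this is wrong:
binarized degree maps carry intrinsic spatial correlation beyond the
applied kernel, because neighbouring voxels share graph edges and
overlapping neighbourhoods. On null cohorts the shortcut produced a
family-wise error rate of about 0.13 instead of 0.05. The default is
therefore to estimate the effective smoothness from the maps' residuals
about their group means (`estimate_smoothness()`): a lag-1 spatial
autocorrelation estimator per axis, inverted against the lag-1
autocorrelation that the package's own discrete kernel would produce on
white noise, so that the simulated null reproduces the measured
autocorrelation exactly rather than through the continuous-Gaussian
approximation. The applied-kernel mode remains available
(`smoothness = "applied"` in `analyze_cohort()`).

**Null model for the statistic.** A single smoothed Gaussian field
thresholded at the z cutoff slightly understates chance cluster sizes for a
low-df t contrast (the shared, spatially smooth variance estimate makes
suprathreshold voxels co-occur). When group sizes are supplied,
`cluster_extent_threshold()` therefore simulates the actual two-sample
statistic: each iteration draws nA + nB independent smoothed noise volumes,
forms the pooled t-map, and thresholds at the t critical value. The classic
single-field z null remains available when no group sizes are given. With
both refinements the measured family-wise error on null cohorts sits at or
below the nominal level; with neither it exceeded twice nominal.

Monte-Carlo thresholds are deterministic given the seed, use 1000
iterations by default (fewer than 100 triggers a warning), and are cached
on all null-distribution-relevant parameters with the estimated FWHM
rounded to 0.5 mm.

# ROC analysis

For every surviving cluster the per-subject mean of the smoothed map over
the cluster voxels is the discrimination score. AUC is the Mann–Whitney U
statistic divided by nA·nB with ties counted 0.5, oriented so AUC ≥ 0.5,
the favoured group recorded. The 95% CI uses DeLong's placement-value
method by default (a seeded percentile bootstrap is the alternative); the
p-value tests AUC = 0.5 by normal approximation. Bands follow the
convention: AUC below 0.7 is "low", 0.7 and above "excellent" (values above
0.9 keep the label).

One caveat is printed deliberately in the documentation rather than
asserted in code: clusters are selected by the same contrast the ROC then
evaluates, so these AUCs are optimistically biased (circular analysis).
The pipeline reproduces that common practice; the numbers are descriptive,
not out-of-sample accuracy.

# The synthetic cohort generator

No acquired data ship with the package; every claim is exercised on
synthetic cohorts that emulate the target study design: two groups of 32
subjects (defaults; tests use 10 per group), 240 volumes at TR = 2 s, a
3 mm standard-space grid, low-frequency signal, and slow motion drifts.
The default desk-scale grid is 20×20×20 voxels so that a full pipeline run
takes minutes, with tissue masks built as concentric shells (gray-matter
core, one-voxel white-matter and CSF shells) around the grid centre —
deliberately simple anatomy that exercises mask plumbing, not realism.

The signal model gives every voxel unit-variance AR(1)-plus-white noise
(lag-1 coefficient 0.3 by default, the two components mixed equally).
Planted structure comes in two forms, per group: *local hubs* (all
gray-matter voxels within a radius of a centre share one source) and
*long-range pairs* (two distant voxel sets share one source). Sources are
Gaussian white noise band-limited to 0.01–0.1 Hz — the band the
preprocessing retains, so planted correlations survive filtering — and
scaled to theoretical unit variance. A member voxel's series is
sqrt(share)·source + sqrt(1 − share)·noise_sd·noise, so at the default
noise_sd = 1 the expected correlation between two co-hub voxels equals the
share exactly; this analytic ground truth is what the calibration tests
assert (mean empirical r within 0.05 of the share at T = 2000). Setting
noise_sd = 0 gives identical member series (r = 1).

Motion traces are smoothed Gaussian random walks anchored at zero, scaled
by motion_severity^1.5: severity 0 is an all-zero trace, the default 1
stays well below the 1.5 mm limit (typical maxima a few tenths of a mm),
and severity near 10 violates it with high probability — so the exclusion
rule can be exercised on demand. Everything is deterministic given the
spec: each subject derives its own 31-bit stream from (seed, group, index).

One gap worth stating plainly: no effect sizes are available for the kind
of group differences the generator emulates, so the planted shares (0.8 in
group A, none in group B, one hub plus one pair) are chosen for test
power, not clinical realism. What passing tests show is that the pipeline
recovers structure of that strength at n = 10 + 10; they say nothing about
sensitivity at clinical effect sizes, and the generator makes no attempt at
physiological noise, EPI distortion, or disease modelling.

# Numerical choices and degenerate inputs

- Distances are Euclidean in world mm through the affine; a pair at exactly
  the sphere radius is local. A 1e−9 tolerance guards floating-point
  boundary cases.
- Z-scoring uses the population SD; an all-zero raw map ("no connections
  above threshold") and a constant raw map (zero SD) are errors, not NaNs.
- The Gaussian kernel is truncated at 4 sigma and renormalized; an FWHM
  below numerical resolution degrades gracefully to the identity.
- Rank-deficient nuisance designs drop aliased columns with a warning
  rather than failing.
- Correlation of a zero-variance series is defined as zero (no edge), and
  the voxel count is logged.
- Cluster peak ties break by lowest linear voxel index, making tables
  deterministic.

# Problem sizes used by the shipped checks

The packaged tests run the oracle-equivalence sweep on grids up to 8³ with
T ∈ {20, 50, 230}; planted-structure recovery on 20 replicate cohorts at
20³, T = 240, n = 10 + 10; and the family-wise-error check on 100 null
cohorts at 16³ with the 1000-iteration null simulation shared across
cohorts (its extent thresholds estimated once, on the first cohort), scales
chosen so the default suite completes comfortably on one CPU. These
are the package's own desk scales; nothing in the method depends on them.
The acceptance script repeats the same computations at 10 planted
replicates and 25 null cohorts.

# Known limitations

- The fixed-sphere lFCD definition is implemented; region-growing lFCD is
  a non-goal.
- Spatial preprocessing (slice timing, realignment, normalization to MNI)
  is out of scope: inputs are assumed on a common grid and motion
  parameters are inputs, not estimates.
- Gaussian-random-field cluster correction is not provided; the Monte-Carlo
  route is the single correction path.
- ROC AUCs inherit selection bias from cluster selection, as above.
- The synthetic generator's masks and noise are idealized; results on real
  data additionally depend on registration quality, physiological noise,
  and atlas choices that the package does not model.
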