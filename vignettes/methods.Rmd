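---
title: "Models and methods behind stereorsa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind stereorsa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stereorsa)
```

`stereorsa` implements the analysis chain for testing whether gender-emotion
stereotype associations bias face representations in ventral temporal cortex
through real-time orbitofrontal feedback, and whether backward masking
abolishes that bias. Because no real dataset ships with the package, every
stage is paired with a synthetic generator that plants a known effect; this
vignette records the models, the parameter choices, and the reasoning behind
the decisions that were genuinely open.

## The behavioral model

### Trajectories and maximum perpendicular deviation

Mouse trajectories live in a standard space with the start button at
(0, 0) and the response targets at (±1, 1.5) — the convention of the
standard mouse-tracking tooling, which the analysis chain assumes
throughout. Preprocessing translates each path to the origin, mirrors it so
the chosen response is on the right, and linearly interpolates to 101
equally spaced time points ("100 time bins" is ambiguous between 100 and
101 points; we take bins-with-inclusive-endpoints, so 101).

**MD definition.** MD is the *signed perpendicular distance at the point of
maximum absolute deviation* from the line joining (0, 0) to the chosen
target (1, 1.5), positive toward the opposite response. Two alternatives
were considered. Taking the maximum *signed* deviation is floored at zero
(the start point lies on the reference line), which contradicts the
empirical fact that MD distributions extend below zero; the
signed-at-max-absolute definition reproduces that behavior and agrees with
the usual definition whenever any deviation toward the opposite side
exists. **max(MD)**, the normalizing constant, is the perpendicular
distance from the reference line to the opposite response location
(3/√3.25 ≈ 1.664) — the farthest meaningful deviation. Negative MD trials
clamp to `md_norm = 0` rather than extrapolating below zero, keeping the
category similarities in [0, 1]; the raw signed `md` is retained alongside,
and it is the raw value the trajectory regression models.

### Synthetic trajectories

Generated trajectories are quadratic Bézier curves whose control point is
displaced perpendicular to the direct path by twice the target MD, sampled
uniformly in time (about 25 samples per trial, i.e. roughly 40–80 ms
spacing at realistic response times). Because the sampled midpoint realizes
the curve's extremum, the measured MD equals the planted value exactly in
the noiseless case — the generator is analytically invertible by the
preprocessing stage, which the oracle tests exploit.

The planted trial-level model is

    MD = baseline + emotion_effect * e + congruency_effect * I(incongruent)
         + moderation * score * I(incongruent) + subject_intercept + noise

with gender/emotion coded −0.5/+0.5. Under that coding the incongruency
indicator equals `0.5 − 2 g e`, so a congruency effect `ce` and moderation
`m` imply a gender × emotion regression coefficient of `−2 (ce + m b̄)` and
a three-way coefficient of `−2 m` (`implied_coefficients()`). Defaults are
sized from the reported study-scale statistics: baseline 0.405, emotion
effect −0.06, `ce = 0.061` and `m = 0.0285` (implying coefficients −0.15
and −0.057 at the mean score 0.49), stereotype score mean 0.49 / SD 0.62,
timeout rate 2.83%, error rate 3.70%.

**Trial noise is mean-one lognormal** (log-scale SD 0.9, i.e. a per-trial
SD near 0.5 at these means, matching the reported condition SDs of
0.49–0.54). Additive Gaussian noise was tried first and rejected: a Bézier
path's measured MD cannot fall below the planted value's sign boundary, so
Gaussian noise censors at zero and attenuates the recovered regression
coefficients by ~20%. The lognormal factor preserves conditional means
exactly (so recovery is unbiased), keeps MD non-negative, and reproduces
the right skew of empirical MD distributions.

### Stereotype score

The score halves the difference of congruent and incongruent pair
correlations so its range matches the published [−2, 2] anchors; the raw
difference (range [−4, 4]) is available with `normalize = FALSE`, since
which scaling the published analysis used is not decidable from the text.
The rating generator builds each subject's four 30-length rating vectors
from orthonormalized latent components, so the noiseless score equals the
planted bias exactly for any bias in [−2, 2]. Rating noise defaults to SD
0.25 on the 1–7 scale: noise attenuates the recovered score by the
classical measurement-error factor, and this default keeps the attenuation
within a few percent. Ratings are clamped (not resampled) to [1, 7];
clamping is symmetric, so the zero-bias regime is exactly unbiased and the
extreme construction still attains ±2.

### Congruency model DM

The hypothesis fixes two cells — congruent pair (angry male, happy female)
at distance 1, incongruent pair (angry female, happy male) at 2. The four
pairs the hypothesis says nothing about (within-sex, within-emotion) sit at
the midpoint 1.5, encoding no directional prediction. The published
bracket notation labels the distances in a way that contradicts its own
accompanying sentence; the sentence (congruent = more similar) is followed.

### Multi-level regression

`gee_gaussian()` is a Gaussian identity-link GEE: iterated generalized
least squares under an exchangeable working correlation with robust
(sandwich) covariance, clusters = subjects. The exchangeable inverse has a
closed form, so the fit uses only cluster sums and scales linearly in
trials. The working correlation choice is not material — robust SEs are
valid under misspecification — and an `"independence"` switch is provided,
under which the point estimates are exactly OLS and the robust SEs are
exactly the clustered sandwich (the cross-check used in the tests, against
the sandwich package). Degenerate inputs: a perfectly fitting model
(residual variance 0) sets the working correlation to 0 instead of
dividing by zero; singular designs are rejected with a rank diagnostic.
Simple slopes at ±1 SD of stereotype strength are linear-combination
contrasts `B_ge + s0 B_ges` with delta-method SEs, equivalent to recentred
refits but exact.

### Signal detection

d′ uses the log-linear correction (add 0.5 to each count, 1 to each total)
so empty cells stay z-transformable; the chance band ±1.74 is treated as a
given constant (its derivation is not stated in the source literature).
Simulated discrimination uses the equal-variance model with a neutral
criterion, P(male | male) = Φ(d′/2).

## The neural model

### Patterns and the HRF

The gamma-variate HRF h(t) ∝ (t/pq)^p e^(p−t/q) defaults to p = 8.6,
q = 0.547 s (the de-facto defaults of this HRF family; peak at
pq ≈ 4.7 s, unit analytic peak, h(0) = 0). Condition regressors are event
boxcars convolved at 16× oversampling and sampled at the TR; nuisance
regressors are accepted as a user matrix (extraction from real data is out
of scope). GLM fitting is per-voxel OLS with t = β/SE; pattern rows are
run-averaged t maps z-normalized across in-mask voxels with the
*population* SD (divide by n), so rows have mean 0 and SD 1 exactly —
convenient for closed-form test assertions; constant maps are rejected
(z undefined).

The pattern generator mixes independent unit-variance voxel components
through the matrix square root of the target correlation matrix
(eigendecomposition, tolerating eigenvalues ≥ −1e−8), so the realized
Pearson-distance DM converges to the target as voxels grow; non-PSD
targets are rejected with the offending eigenvalue.

### RSA

DMs are vectorized in one fixed pair order (row-major lower triangle of
the labelled matrix) shared by every module. Spearman RSA uses
average-rank ties; regression RSA rank-transforms all vectors and fits
OLS with an intercept (whether the published rank regression included one
is unstated; including it is standard practice). With six pairs and no
ties, the no-covariate regression slope *is* Spearman's rho, an identity
asserted in the tests. Negative betas are reported as-is.

A genuine degeneracy deserves note: subjective DMs share their gross rank
structure across subjects, and occasionally a subject's 6-pair rank order
exactly duplicates the group average's, making the rank regression
singular. `regression_rsa()` diagnoses this as an error; `run_pipeline()`
drops such subjects from regression-RSA summaries and reports how many
(`n_dropped_collinear`). The recovery simulations instead plant
idiosyncratic random subject DMs (`gen_subject_dms()`), for which the
collision has negligible probability.

The masked-condition null is planted by blending each subject's DM with
the group structure at weight 0 (`blend_dms()` on the correlation scale,
which preserves positive semi-definiteness); the unmasked arm uses a
per-subject weight that also scales that subject's PPI coupling, creating
the planted connectivity-representation link.

### Searchlight and permutation inference

Spheres use inclusive Euclidean membership on voxel indices (radius 3 →
123 voxels, matching the printed count) and *shrink* at mask borders
(sphere ∩ mask, with the per-center size recorded) rather than skipping
border centers; centers with fewer than 2 usable voxels are missing (NA),
not zero. The implementation accumulates the 15 sufficient statistics of
the pairwise correlations by shift-and-add over sphere offsets, so a
volume is processed in a handful of vectorized passes rather than
per-center loops.

Smoothing is a fixed separable Gaussian with σ = FWHM/(2√(2 ln 2)),
mask-aware renormalized (smoothed map divided by smoothed validity mask),
so constants are preserved and edges are not dragged toward zero. This is
a fixed-kernel approximation of iterative smooth-to-target-FWHM tools.

Group inference is sign-flip max-statistic permutation on the one-sample
t map: the null flips whole subject maps, each voxel's family-wise
corrected p is the rank of its observed t in the null distribution of the
image-wide maximum, with the identity permutation counted
(p = (1 + #{max ≥ t})/(n_perm + 1), guaranteeing validity). The statistic
is one-sided (positive t), matching the directional RSA hypothesis the
maps test. Threshold-free cluster enhancement is deliberately not
implemented; the max-statistic correction is the corrected-inference
surface. Because sign flips leave voxelwise sums of squares unchanged,
the permutation t maps are computed from a single signs × maps matrix
product, which is why 5000 permutations are cheap. A separate
`cluster_threshold()` utility (6-connectivity, minimum extent) supports
liberal seed-region definition from univariate contrasts.

### PPI

Deconvolution inverts the HRF convolution matrix with a ridge penalty
λ = ridge × trace(K'K)/T (trace-normalized so `ridge` is unitless;
default 1e−3 — the tool the published analysis names does not state its
regularization). The interaction term is formed at the neural level
(deconvolve, multiply by the −1/+1 masking regressor, reconvolve); a
`"bold"`-level product switch is provided since the published order of
operations is not fully specified. Runs are single-condition, so the
psychological regressor is block-constant at volume resolution. A constant
condition regressor makes the interaction collinear with the seed and is
rejected. The linkage analysis is a one-tailed Pearson correlation
(directional hypothesis r > 0) between per-subject interaction betas and
[unmasked − masked] RSA-beta differences.

## What the generator emulates — and what it does not

Emulated: the 2 × 2 design with 35 faces per cell (140 faces, 280
mouse-tracking trials, 120 rating trials, 2000 ms trials, 77 null events
per run, masked runs first); trajectory deviation scaling with congruency
and stereotype strength; rating structure with a planted score;
condition-pattern correlation structure; seed-target BOLD coupling
modulated by masking; volumes with signal regions embedded in noise.

Not emulated: face images; physiological fMRI noise (drift, motion,
autocorrelation — GLM residuals are white by construction, so prewhitening
is out of scope); whole-brain-scale volumes; optimized event sequences
(schedules are seeded random permutations; estimation efficiency is not a
tested property). Passing recovery tests therefore demonstrates the
*correctness of the analysis chain*, not robustness to realistic fMRI
artifacts.

## Problem sizes and runtime

The test suite's simulation sizes are chosen to make each property
decisive at desk scale: 100 replicates of 100-subject studies for GEE
coverage; 34 subjects × 300 voxels for RSA arm recovery; 200 reruns of
10-subject 12³ null grids at 300 permutations for family-wise error
calibration; 16³ grids for searchlight recovery. The full default pipeline
(34 subjects, 14³ grid, 500 permutations) completes in well under a
minute on one CPU.

## Known limitations

- The stereotype score is attenuated by rating noise (classical
  measurement error); the default noise keeps this within a few percent,
  but users raising `noise_sds$rating` should expect proportional
  shrinkage.
- Searchlight beta maps are spatially correlated by construction
  (overlapping spheres), so map-level summaries have far fewer effective
  degrees of freedom than voxels.
- The GEE is Gaussian identity-link only — sufficient for MD, not a
  general GEE.
- The exchangeable moment estimator of the working correlation can be
  slightly biased in very small samples; robust SEs absorb this.
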