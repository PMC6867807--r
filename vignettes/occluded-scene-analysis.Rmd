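---
title: "Decoding and modeling cortical feedback with occluded scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding and modeling cortical feedback with occluded scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

When a quadrant of a visual scene is covered by a uniform white occluder,
the patch of retinotopic early visual cortex (V1/V2) that maps to that
quadrant receives no informative feedforward input. Any stimulus-specific
structure in its activity must arrive through non-feedforward routes --
cortical feedback carrying the brain's internal model of the missing scene
region. `scenefeedback` implements the full analysis chain used to probe
such feedback signals: multivoxel decoding of scene identity, category and
depth from occluded-region voxel patterns; representational similarity
analysis (RSA) that fits image-computable feature models to cross-validated
pattern dissimilarities; and behavioral analyses linking observers' line
drawings of the occluded region to the robustness of the cortical
representation.

Because raw fMRI data for this paradigm are not generally available, the
package is built around a synthetic-data module that generates every input
the analyses need -- scenes, drawings, rater scores and voxel patterns --
with known ground truth, so each estimator can be validated by parameter
recovery. Real data enter through the same interfaces (PNG/TIFF images,
PNG drawings, TSV beta tables).

## The synthetic generator and what it emulates

`generate_scene_set()` produces grayscale oriented-texture mosaics rather
than photographs: each of the K categories has a dominant orientation and
spatial frequency, and each scene adds its own phase, frequency jitter and
smoothed noise. This preserves exactly the property the downstream math
relies on -- category-discriminable, scene-specific image statistics --
while remaining freely redistributable. The display geometry follows the
original paradigm: a 19.5 x 14.7 degree field of view, occluder over the
lower-right quadrant, and a default raster of 256 x 192 px standing in for
1024 x 768 at the same aspect ratio (degrees per pixel = 19.5 / width).
The visual-field convention is degrees from fixation, x rightward, y
upward; the lower-right quadrant is \{x > 0, y < 0\}.

`generate_voxel_patterns()` plants three latent components per subject,
all i.i.d. standard normal across voxels (the simplest geometry whose
effect sizes are directly controllable): a scene-specific vector, a
category vector and a depth gain. The beta for a trial showing scene *s*
at voxel *v* is

  gain_roi x (w_scene u_s[v] + w_cat c_cat(s)[v] + w_depth d(s) g[v]) + N(0, noise_sd)

with d(s) = +1/-1 for Far/Near. The per-voxel signal-to-noise ratio of
the original experiment is unknown, so the defaults (w = (1, 0.5, 0.5),
noise_sd = 3, occluded gain 0.35) were chosen once so that occluded-ROI
decoding lands clearly above chance while remaining far below non-occluded
decoding -- the qualitative ordering the paradigm is designed to expose.
Voxel pRFs are drawn uniformly inside their ROI's quadrant with a
2-sigma containment margin, so every generated voxel passes the
containment filter it would be subjected to in a real dataset. BOLD
time-series simulation (physiological noise, scanner drift) is
deliberately out of scope: the generator produces GLM-level betas.

Observer line drawings are built from a per-scene stroke template: each
observer keeps each template stroke with probability `consistency` and
adds Poisson-many idiosyncratic strokes with mean proportional to
1 - consistency. At consistency 1, all observers are identical. One
caveat worth knowing: even "independent" stroke drawings share a spatial
density profile (random line segments cross central pixels more often
than corners), so their split-half correlation has a small positive
bias -- a property real drawings share, since observers also share a
canvas prior. The package's null tests therefore use pixel-wise random
rasters when a strictly zero-correlation reference is needed.

Depth ratings are lognormal around class centers of 10 m (Near) and
1000 m (Far) on the log10 scale; predictability ratings couple the 1..7
scale to the generator's per-scene consistency.

## Feature models

* **Gist** (`gist_descriptor`): log-Gabor energy in a 4 x 4 spatial grid,
  8 orientations, 4 scales = 512 channels. The reference implementation's
  filter constants are not published as formulas, so the bank is specified
  here explicitly: center frequencies log-spaced over 0.02-0.3
  cycles/pixel, ~1 octave radial bandwidth, orientation bandwidth
  0.6 pi / n_orientations, one-sided in orientation so the squared complex
  magnitude is a true quadrature energy envelope. Nyquist frequencies are
  zeroed, which keeps the bank exactly equivariant under 90-degree image
  rotation (a property the test suite checks channel by channel).
* **Weibull** (`weibull_stats`): maximum-likelihood Weibull scale (beta)
  and shape (gamma) of Gaussian-derivative contrast magnitudes within
  central regions extending 1.5 and 5 degrees from fixation. The source
  description names the X/Y-cell analogy but not the filter or fitting
  method; first-order Gaussian derivatives with MLE fitting are used, and
  correctness is asserted by parameter recovery (within 2% at n = 1e5)
  and scale equivariance, not by reproducing any published coefficient.
  Fits normalize by the mean contrast first (the MLE is scale-equivariant),
  which keeps the optimizer stable at arbitrarily low contrast.
* **HMAX C2** (`learn_prototypes`, `hmax_c2`): Gabor S1, local max-pool
  C1 over position and adjacent filter sizes, Gaussian RBF match to
  stored C1 prototypes, global max per prototype. Desk-scale defaults are
  50-200 prototypes, two patch sizes, 4 orientations and 2 scale bands;
  2000 prototypes are supported through the same interface when fidelity
  matters more than runtime. Prototypes must come from images outside the
  evaluated set; the pipeline uses a held-out synthetic scene set.
* **Category** (`category_model_rdm`): binary same/different-category
  dissimilarity (0 within, 1 between).
* **Depth** (`depth_model`): log10 ratings, 1000 bootstrap samples of the
  mean, normal fit; the single channel is the distribution mean and the
  model RDM is the squared mean difference.

Per-channel model RDMs are squared Euclidean differences of single
channels, giving the 276-pair x channels design used in model fitting.

## Response modeling

The two-gamma HRF uses the common default constants (peak 6 s,
undershoot 16 s, ratio 6), since "standard two-gamma" fixes no numbers;
it is implemented as a difference of gamma densities with unit rate and
peak-normalized to 1. Designs are boxcars convolved on a 0.1 s grid and
sampled at the TR; single-block betas come from an ordinary least-squares
GLM with intercept.

ROI handling treats the localizer-contrast step of a real experiment as
label-based selection (synthetic voxels carry ground-truth ROI labels);
pRF containment is the geometric criterion that matters and is
implemented exactly: a voxel survives when the disk of radius 2 sigma
around its pRF center lies inside the quadrant. The description of the
containment radius in the source material prints a gamma where the pRF
literature uses sigma; it is read as 2 sigma. Border shrinking moves
*both* interior borders of the occluded quadrant (the two fixation axes)
inward -- which edges shrink is not specified upstream, and both-edges is
the conservative reading; the choice is isolated in `shrink_roi()`.

## Decoding

`loro_decode()` z-scores each trial vector across voxels (per trial, not
per fold, so the normalization cannot leak fold information), then runs a
linear SVM (C = 1, no hyperparameter search) in a one-vs-one pairwise
multiclass scheme with majority voting; vote ties are broken by summed
signed decision values. Cross-validation is leave-one-run-out.
Permutation nulls shuffle training-fold labels only, leaving test labels
intact, and use the add-one p-value rule. Cross-classification holds out
one scene per category (18 training scenes) or per depth class (22),
averaged over 100 random hold-outs by default. Group-level inference is
the exact one-sided Wilcoxon signed-rank test against chance; only the
border-shift family is FDR-corrected.

## RSA

Data RDMs use the cross-validated linear discriminant contrast (LDC):
for each scene pair, the two halves' mean-pattern differences are
combined through a noise precision, divided by the voxel count, and
averaged over both directions. The noise covariance is diagonal with
per-voxel residual variances shrunk toward their mean (weight 0.2), with
an identity fallback flag for degenerate designs; the source names LDC
but not a covariance estimator, and a diagonal-shrinkage estimator is
the standard robust choice at these trial counts. LDC entries can be
negative and are unbiased under the null -- both properties are tested
by simulation.

The 70 cross-validation plans are all ordered (fit-half, test-half)
choices of 4 runs from 8 -- C(8,4) = 70 is only consistent with the
ordered reading. Quarters within a half follow a fixed canonical rule
(sorted runs alternate), and each half contributes a single
quarter-vs-quarter LDC RDM. Model fitting is leave-one-scene-pair-out
non-negative least squares: for each pair, weights are fit on the 231
pairs not involving either scene and the held-out entry is predicted.
Because LDC values carry an arbitrary offset relative to model units, the
NNLS design includes an unconstrained intercept (a +1/-1 column pair);
non-negativity applies to model channels only. This is a documented
design choice, not something the source specifies. One visible
consequence: a channel whose weight is clamped to zero yields
predictions equal to each fit subset's mean, which differ slightly
across held-out pairs rather than being globally constant.

Predicted and test RDMs are compared with Kendall's tau-a (all-pairs
denominator, so ties are penalized), implemented by direct pair counting
and verified against brute force. Noise ceilings are the standard mean /
leave-one-subject-out correlations with the group-average RDM. The
sliding-window analysis evaluates models in 17 bins of 8 scenes ordered
by predictability and corrects the per-bin paired Wilcoxon tests across
bins with Benjamini-Yekutieli FDR (bins overlap, so the
dependence-robust procedure is required); the normal approximation is
used for these paired tests since exact p-values are undefined under
ties.

## Behavioral analyses

Average drawings are pixelwise means scaled jointly across the whole
scene set (a single min-max, preserving between-scene darkness).
Split-half drawing consistency downsamples to 24 x 32 by area averaging
(box filter -- the target size is specified upstream, the kernel is not;
area averaging conserves stroke mass), splits observers 23/24, correlates
subgroup averages per scene, and averages Fisher-z values over 1000
resamples, with |r| capped at 0.999999 so that identical synthetic
observers do not produce infinities. Consistency is compared with
per-scene decodability summarized as the row mean of a subject's
full-data LDC RDM (whether the original summary used full-data or
split RDMs is unstated; full-data row means are used and the choice is
confined to one argument). The consistency-to-model-advantage slope is a
linear mixed model with random intercept and slope per subject, fit with
`lmerTest` (Satterthwaite t and p); what the package guarantees is the
contract -- fixed-slope t and p, singular fits flagged, single-subject
input degrades to ordinary regression -- not a particular optimizer.

## Problem sizes and runtime choices

The packaged demo profile (`run_config()` defaults) uses 6 subjects, 4
runs, 200 voxels per ROI, 50 prototypes and 200 permutations, which
completes in minutes on one CPU. The test suite validates the estimators
at smaller sizes still sufficient for each property: LDC calibration with
500 simulations, Weibull recovery at n = 1e5, tau-a against brute force
up to n = 12, decoding monotonicity on a 3-point effect grid with 10
replicates. Permutation-null convergence is checked with 200 shuffles,
where the binomial standard error of the null mean is well under 0.1
percentage points.

## Known limitations

* Synthetic scenes are texture mosaics: feature models can discriminate
  categories, but absolute Gist/Weibull/HMAX values are not comparable to
  natural-image statistics, and analyses that depend on natural-scene
  regularities (e.g. specific Weibull beta/gamma ranges) only exercise
  recovery properties here.
* The generator plants linear, additive pattern components with Gaussian
  noise; nonlinear voxel selectivity, temporal autocorrelation and motion
  artifacts are absent, so passing tests show estimator correctness, not
  robustness to every real-data pathology.
* pRF estimation itself is out of scope; pRFs are metadata supplied with
  the patterns.
* The permutation machinery refits the SVM for every shuffle; at the full
  1000-shuffle, 18-subject scale of a real study this is hours of CPU,
  and the package makes no attempt to parallelize it.
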