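---
title: "Mapping learning-induced brain plasticity: models and methods"
author: "plastimap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping learning-induced brain plasticity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastimap)
```

# Scope

`plastimap` implements the two computational arms of a longitudinal
motor-learning plasticity study in the mouse, together with the densitometry
and behavioral scoring that tie them to biology:

1. **Voxelwise time-course morphometry.** Modulated gray- and white-matter
   volume maps acquired over six sessions are analyzed voxel by voxel with
   linear mixed models, comparing three candidate trajectories of
   learning-induced change and mapping where each is supported.
2. **3D reconstruction of myelinated axons.** Confocal stacks of
   MBP-immunolabeled cortex are denoised, binarized, reduced to centerlines
   with local radii, and quantified as length density, mean diameter and
   volumetric fraction within the well-labeled section depth.

Every analysis stage is driven by a seeded synthetic-data generator that
emulates the corresponding data modality with known ground truth, so the
whole pipeline is testable without any imaging data.

# Trajectory models and voxelwise mixed models

## Time-course bases

Three shapes span the hypotheses about how a voxel's tissue volume changes
over a training horizon of `T = 14` days (sessions on days 0, 2, 6, 8, 10,
14), all anchored at 0 on day 0 and bounded by 1:

* linear, `f(t) = t/T`: steady drift;
* asymptotic, `f(t) = 1 - (1 - t/T)^2`: change that stabilizes (zero slope
  at `T`), the signature of expansion followed by retention;
* quadratic, `f(t) = 4t(T - t)/T^2`: change that renormalizes toward
  baseline, peaking mid-training.

The shapes are deliberately two-parameter-comparable: each contributes one
fixed-effect regressor, so AIC comparisons across shapes compare equally
complex models. Decreases are not separate bases; the signed interaction
coefficient covers both directions, and significant voxels are split by
sign afterwards.

## The per-voxel model

At each voxel the response `y` (modulated tissue volume) over subjects `i`
and sessions `t` is fitted by maximum likelihood with `lme4`:

```
y_it = b0 + b1 TIV_i + b2 group_i + b3 f(t) + b4 group_i f(t)
       + u0_i + u1_i f(t) + e_it
```

`group` is 0 for non-trained controls and 1 for trained animals; TIV (total
intracranial volume, mm^3) absorbs head-size differences; `u0, u1` are the
subject random intercept and random slope on the trajectory regressor. The
group-by-time coefficient `b4` (exposed as `beta3`, the conventional name
for the interaction of interest) is the learning effect. A group main
effect is included even though time-invariant offsets are largely absorbed
by TIV and the random intercepts: it protects the interaction test against
baseline group differences.

Three choices deserve justification:

* **ML, not REML.** Model selection compares fits with different
  fixed-effect structures (the three shapes); only ML log-likelihoods are
  comparable across those, and the AIC/AICc machinery consumes them
  directly. `k` counts fixed effects plus variance components (9 for the
  full model).
* **Wald t with between-subject degrees of freedom.** The interaction is a
  group contrast on subject slopes, so its natural denominator degrees of
  freedom under the containment convention is the number of subjects minus
  the two slope-stratum fixed effects. A normal reference is visibly
  anti-conservative in the far tails that drive voxelwise FDR: on null
  phantoms it produced spurious map-wise discoveries that the t reference
  eliminates.
* **Unbalanced panels.** Missing subject-sessions are simply dropped from
  the long-format panel; the mixed model handles the imbalance. Degenerate
  voxels (zero response variance) are flagged with the convention p = 1,
  non-converged voxels are excluded from maps, and both are listed in the
  QC table of the result object.

The mass-univariate driver reuses one lme4 deviance function per shape and
swaps the response in place, warm-starting the optimizer from the previous
voxel; this is numerically identical to calling `lmer()` per voxel (tested
to 1e-4 in log-likelihood against a brute-force marginal-likelihood
maximization) and about five times faster. A 20^3 grid with 40 subjects and
three shapes fits in roughly four minutes on one core; the packaged tests
and acceptance checks use that size.

## Maps, FDR and model preference

Per shape, interaction p-values across in-mask voxels are corrected with
classic Benjamini-Hochberg step-up FDR (no dependence correction, matching
the plain "FDR correction" convention) at a configurable level; the
significant set is split by interaction sign into increases and decreases.
Cluster volumes are reported as voxel count times the cube of the 0.08 mm
voxel size. The preferred-model map labels a voxel with a shape only when
its AIC undercuts every other shape's by more than `deltaAic` (default 10);
anything less decisive stays unlabeled.

VOI trajectories (`extractVoi`) are session means over a mask, normalized
to the control-group mean of the same session, so controls sit at 1 by
construction. Per-subject shape support (`subjectTrajectoryAicc`) uses
ordinary least squares on the subject's own trajectory with k = 3
(intercept, slope, residual variance); pairing the asymptotic AICc with
behavioral learning rates gives the individual-differences correlation.

## Model comparison

AICc applies the standard small-sample correction
`AICc = -2 logL + 2k + 2k(k+1)/(n-k-1)`; it requires `n > k + 1` and decays
to AIC with n. Two models are compared through the Akaike probability
`p = exp(0.5 D) / (1 + exp(0.5 D))` with `D` the AICc difference; `D = 2`,
the customary decisiveness threshold, corresponds to 73.11% evidence. In
serialized comparison tables the preferred row carries its probability
against the runner-up and every other row its probability against the
preferred model, so two-model tables print the familiar complementary
percentage pairs.

# Fiber reconstruction

## Preprocessing and binarization

Denoising follows the edge-preserving protocol of the source workflow:
anisotropic diffusion for a total time of 25 in steps of 5, then a 5x5x5
Gaussian of unit voxel SD. The diffusion is Perona-Malik with exponential
conductance; the published tool setting fixes only total time and step, so
the contrast parameter `kappa = 30` (about 12% of the 8-bit range) was
chosen so that fiber-background edges (contrast > 100) are preserved while
shot noise (fluctuations < 30) diffuses away. Each nominal step is
sub-stepped to satisfy the explicit-scheme stability bound; the result is
independent of that implementation detail up to numerical error.
Binarization maximizes between-class variance over the 256-bin histogram
(Otsu), foreground above the threshold; the search is exact and is tested
against an exhaustive oracle and an independent implementation.

## Skeletonization

Centerlines come from sequential removal of *simple points* — voxels whose
deletion provably preserves topology under the (26, 6) foreground /
background connectivity pair — in six directional subiterations, never
removing curve endpoints. Because every deletion is re-verified on the
current image, topology preservation holds by construction: segments never
split, loops and components survive (verified on cylinder, torus and
disjoint-tube phantoms via Euler characteristics). Two practical
refinements matter at probe boundaries and crossings:

* **In-plane boundary padding.** Fibers cut crosswise by the lateral probe
  limits would otherwise erode by about one tube radius before an endpoint
  forms; replicating the boundary cross-section outward (6 voxels) and
  cropping afterwards lets centerlines run to the probe edge. The z faces
  are never padded: there fibers are cut lengthwise by the section surface,
  and extruding them would displace their centerlines into the padding.
* **Junction consolidation.** Crossing fibers thin to small clusters of
  branch voxels connected by sub-voxel fragments; compact clusters
  (bounding diagonal up to 0.6 um) are contracted to their centroid so that
  crossing fibers meet at a point instead of fragmenting. Extended junction
  complexes keep their voxel structure, since contracting them would
  discard genuine path length.

Terminal side-branches shorter than 1 um (a configurable prune) are treated
as thinning artifacts, mirroring the undocumented pruning of the commercial
tool.

## Nodes, radii and metrics

Each traced segment is re-parameterized by arc length with nodes every
0.5 um (the count is rounded so realized spacing stays within 20% of
nominal; segments between 0.4 and 0.5 um keep their two endpoints, shorter
ones collapse to a midpoint node). Node radii are the anisotropic Euclidean
distance transform — computed on the native 0.18 x 0.18 x 0.48 um grid, no
resampling — interpolated at the node, minus half an in-plane voxel so the
fiber surface sits halfway between the last foreground and first background
voxel; an isolated single-voxel line therefore reports half an in-plane
voxel, and radii are floored just above zero.

Quantification is restricted to the labeled depth: per raw (pre-smoothing)
z-slice the 0.99 intensity quantile is computed, and `Thref` is the
contiguous run of slices above 75/255 counted from the labeled surface
(slices beyond the first gap never count; the brighter stack face defines
the surface). Probes with `Thref <= 2 um` are excluded. The quantification
volume adds a 0.5 um border correction, `V = A (Thref + 0.5)`, for
structures bordering the probe limits; the uncorrected density is also
reported since printed summary depths in the field are ambiguous about the
correction. Length density is in-depth centerline length over `V`; mean
diameter averages twice the node radius over in-depth nodes; volumetric
fraction integrates `pi r^2` along the in-depth arc (trapezoid in `r^2`)
over `V`, capped at 1.

# Densitometry

Sections are segmented into three intensity classes — background,
autofluorescent tissue, specific myelin signal — by exact exhaustive search
over all 256-bin threshold pairs maximizing between-class variance. The
specific signal is the top class: immunoreactivity is its mean intensity
and `specificFraction` its area fraction; both are reported because tools
differ on whether "signal" means the class mean or its area. Per-subject
values average immunoreactivity over the subject's sections, unweighted.
ROIs are polygons rasterized by point-in-polygon tests on pixel centers.

# Behavior

A reaching session scores: success (valid successful trials over completed
trials; trials with abnormal behavior are invalid and never count as
successes), accuracy (successes over attempts pooled across successful
trials — the ratio-of-sums reading of "normalized by the number of
attempts", robust to single-trial outliers; the per-trial mean-of-ratios
alternative is reported alongside), and first-attempt success. The learning
rate is the OLS slope `b` of `success% = a + b log(day)` with day indexed
from 1.

# Synthetic data: what it emulates, and what it does not

All generators take a seed and reproduce byte-identically; each emits its
ground truth alongside the data.

**Longitudinal volumes** (`simLongitudinalVolumes`): constant baseline
field 0.8 (a typical modulated value), subject random intercept (SD 0.02)
and random slope (SD 0.01), Gaussian noise SD 0.01, a group-by-time effect
of a few percent (default -4%, the magnitude seen in cortical VOI
trajectories) confined to a 5^3 block of a 20^3 grid, 20 subjects per
group, TIV ~ N(415, 20) mm^3 — a realistic mouse intracranial volume.
Amplitude 0 gives null phantoms; a `dropout` option emulates designs whose
per-session n grows over training. Not emulated: spatial noise correlation,
registration artifacts, bias fields. FDR control shown on these phantoms
therefore speaks to the independence-ish regime; smoothed real maps are
spatially correlated, for which classic BH remains valid but conservative
claims about realized FDP do not transfer verbatim.

**Confocal probes** (`simFiberStack`): smooth, mostly in-plane random
fibers of radius 0.45 um rasterized on the anisotropic grid; depths
stratified across the labeled band starting at the cut surface so every
labeled slice carries signal; fibers keep a clearance of one diameter
(solid axons exclude each other; interpenetrating fibers would make the
ground-truth length unrecoverable in principle, since a centerline of the
union counts an overlap run once) plus the PSF footprint, the usual
resolvability convention for quantitative validation phantoms —
candidates violating it are redrawn. Labeling decays below a 4.8 um plateau with a 1 um
exponential tail (antibody penetration); a Gaussian PSF (0.1 um lateral,
0.25 um axial — a high-NA oil objective at ~550 nm) and Poisson photon
noise complete the imaging model. The default field (17 x 17 um, 10
fibers) puts the volumetric fraction near 5-7%, the upper range of
intracortical myelin; an earlier, denser draft (~13%) produced unphysical
merge rates at crossings. Not emulated: nodes of Ranvier, variable radii
along fibers, depth-dependent PSF broadening, autofluorescent structures.

**Sections** (`simSection`): three-class mixture at means 20/90/200 with
smooth-field spatial structure (streak-like specific class) and Gaussian
noise SD 8. **Behavior** (`simBehaviorSessions`): saturating daily success
probability `p0 + (pMax - p0)(1 - exp(-rate d))`, 30 Bernoulli trials per
day, geometric attempt counts, 5% invalid trials.

# Numerical choices and degenerate inputs

* AICc errors when `n <= k + 1`; comparison ties (to within 1e-9) break
  toward the model with fewer parameters.
* BH-FDR with m = 1 reduces to the raw threshold; empty p-vectors give
  empty masks; NA p-values (QC-flagged voxels) are never rejected.
* Gaussian smoothing uses half-sample symmetric padding, which preserves
  the volume total to numerical precision; `fwhm = 0` is the identity.
* Otsu requires a non-constant image; three-class Otsu requires three
  distinct values.
* Empty skeletons yield zero densities and a missing diameter; rejected
  probes raise a typed `excludedProbe` condition that the pipeline converts
  into an `accepted = FALSE` record.
* The thinning order (six fixed directions, fixed scan order) makes
  skeletons exactly reproducible but only approximately symmetric:
  transposing a stack's in-plane axes changes removal order and perturbs
  metrics by well under a percent, which is the tolerance the invariance
  test uses.

# Problem sizes used in the packaged checks

The test suite and acceptance checks run phantom recovery at 20^3 voxels
with 40 subjects (the statistical arm), twenty 96 x 96 x 30 probes (the
fiber arm), 100-image oracle equivalence for the threshold searches, and
200 simulated animals for behavior — sizes chosen so the full suite
completes in well under half an hour on a single core while every claim is
still exercised end to end.

# Known limitations

* Tangential fiber contacts closer than the imaging resolution still merge
  into one centerline; the generator avoids true interpenetration but
  cannot make near-contacts resolvable, which bounds length-density
  accuracy at high myelin densities.
* The asymptotic and quadratic bases are fixed shapes, not free-rate fits;
  subjects whose plateau falls outside the 14-day window are absorbed by
  the closest fixed shape.
* Wald-t inference with containment df is an approximation; Satterthwaite
  or Kenward-Roger corrections would be preferable at very small subject
  counts but are an order of magnitude slower per voxel.
* The densitometry "specific signal" convention (top class) is the only
  monotone choice but remains a convention; both the class mean and its
  area fraction are exposed so either reading can be audited.
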