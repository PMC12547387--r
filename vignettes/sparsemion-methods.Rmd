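---
title: "Models and methods behind sparsemion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind sparsemion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sparsemion)
```

# The analysis problem

`sparsemion` implements a complete analysis chain for auditory task fMRI in
anesthetized macaques acquired with a blood-pool contrast agent (MION) under
a clustered sparse temporal sampling design, together with a synthetic-data
generator that emulates the acquisition and signal structure so every stage
can be exercised and calibrated without animal data.

Two features make this setting unusual among fMRI pipelines:

* **Reversed hemodynamics.** MION is a cerebral-blood-volume (CBV) contrast
  agent: neural activation increases blood volume and *decreases* the
  measured signal. The response function is therefore negative, with a long
  tail and no undershoot.
* **Non-uniform sampling.** To present sounds without scanner noise, volumes
  are acquired in bursts ("clusters") of 7 volumes spaced 646 ms apart,
  separated by 3.5 s scanner-silent gaps in which one stimulus (or silent)
  block is presented. Regressors must be evaluated at these irregular
  acquisition times rather than on a uniform TR grid.

# The acquisition model and the synthetic generator

A run consists of 48 cycles, each a 3.5 s silent gap followed by a
7-volume acquisition cluster (48 x 7 = 336 volumes). Each gap hosts one
block: 32 stimulus blocks (4 per each of 8 sound subcategories, nested in 2
main categories — macaque vocalizations and non-vocal sounds) and 16 silent
blocks, in a seeded uniform random order under those count constraints.
Stimulus blocks contain 6 stimuli of 0.5 s separated by 50 ms, and start
100–250 ms (uniform jitter) after the end of the previous cluster. Run
duration is derived from the schedule (48 x 8.022 s = 385.1 s); the
protocol's nominal "7 minutes" is treated as a rounded description, as is
the "4.6 s" cluster duration (7 x 646 ms = 4.522 s).

The generator plants known ground truth on a tissue/region phantom:

* **Regions.** Spherical gray-matter blobs named for the fields they
  emulate: bilateral A1-like auditory cortex (responds to all 8
  subcategories, +1% signal change), an IC-like midbrain blob (+0.8%),
  bilateral F5-like and pMTG-like regions (+0.5% to vocalizations, −0.5% to
  non-vocal sounds), and an aTVA-like region (+0.4% to vocalizations only);
  plus white-matter and CSF slabs.
* **Signal.** `baseline x (1 + amplitude/100 x regressor(t))`, with the
  regressor already carrying the negative response function, so a positive
  *neural* amplitude darkens the image. Baseline is 1000 arbitrary units.
* **Noise.** Per-voxel AR(1) noise (default lag-1 correlation 0.3, marginal
  sd 20 units = 2% of baseline — a realistic single-voxel EPI noise level),
  plus random per-voxel polynomial drift (orders 1–3, RMS amplitudes 1%,
  0.5%, 0.3% of baseline).
* **Compartment nuisance.** Latent "physiological" time courses (default
  two per compartment, AR coefficient 0.6, i.e. decorrelating over a few
  volumes, like aliased respiratory/cardiac fluctuations) load coherently
  (positive mean, 30% spatial variation) on white-matter and CSF voxels at
  full strength and on gray matter attenuated by a `gray_leak` factor
  (default 0.3). The leak embodies the CompCor premise — compartment
  signals are clean measurements of fluctuations that also contaminate gray
  matter. Two properties were found to be *necessary* for component-count
  optimisation to behave like it does on real data: coherent (not zero-mean
  i.i.d.) loadings, since otherwise the whole-brain maximum t simply
  relocates to barely-contaminated voxels and denoising never helps; and
  latents faster than the block-design timescale, since near-drift latents
  are collinear with the task regressors and removing them can genuinely
  *lower* the objective. Slow confounds are the drift model's job.

One master seed expands into per-run sub-seeds through a documented integer
hash (`derive_seed()`), so any run is regenerable in isolation, and
identical seeds give bit-identical cohorts. Default cohort size matches the
study: 11 subjects, run counts drawn from 10–14 (median 12 in expectation).

What the generator does **not** emulate: head motion, field inhomogeneity
and distortion, multiband reconstruction artifacts, spatially varying
hemodynamics, non-Gaussian noise, registration error (data are generated
pre-aligned), or any audio content — stimuli exist as labels and timings
only. Passing tests therefore validate the *statistical machinery* under
the stated noise model, not robustness to those real-data complications.

# The response function and task regressors

The impulse response is a sign-flipped gamma-variate kernel,

$$h(t) = -c\,(t/\theta)^{k-1} e^{-t/\theta},$$

with shape $k > 1$ (default 3), timescale $\theta$ (default 4 s), support 60
s, and $c > 0$ fixed by unit-peak (default) or unit-area normalization. The
functional form guarantees the qualitative constraints of a CBV response —
single extremum at $(k-1)\theta$ = 8 s, no undershoot, monotone long tail —
by construction. The exact analytic form and parameters of the response
used on the real data are not published; these defaults are a stated
convention, not a reconstruction, and all parameters are configurable.

Task regressors are block boxcars on a 10 ms grid (fractional coverage at
block edges, making the rectangle-rule convolution second-order accurate),
convolved with the kernel by FFT and read off at the acquisition timestamps
by linear interpolation. Regressors are invariant to halving the grid step
to well below the protocol's finest timing (50 ms). Silence is the implicit
baseline and receives no column.

Because the negative kernel is baked into the regressors, fitted
coefficients and t maps come out in *neural* polarity (activation
positive), matching the polarity convention of published CBV maps.

# The per-run GLM

The design matrix holds the task columns (8 subcategories, or 2 main
categories, per model), orthogonal-polynomial drift per run (default cubic,
the convention of the GLM package family this pipeline follows; always
including the constant) and any nuisance columns. Two separate GLMs are
fit: the 2-category model supplies the Sound-vs-Silence and
Macaque-vs-NonVocal contrasts; the 8-subcategory model supplies the ROI
profiles.

Fitting is ordinary least squares followed by AR(1) prewhitening: the lag-1
autocorrelation is estimated per voxel from OLS residuals, **bias-corrected**
for the projection (residuals of a 12-column fit lose low-frequency
autocorrelation; the expectation of the naive estimator is a ratio of
polynomials in the true coefficient whose coefficients are diagonal sums of
the residual-forming matrix, tabulated once per design and inverted),
spatially regularized with the same 3 mm kernel used for the data (a
standard stabilization, switchable off), binned at 0.01 resolution, and
applied as a per-bin whitening transform before refitting. Degrees of
freedom are `n − p`.

**Percent-signal-change convention.** Effects are scaled by the GLM's own
intercept — the estimated *silence baseline* — rather than by the run's
temporal mean. With a reversed-sign agent the temporal mean is itself
depressed by the task response (by about 4% per 1% amplitude under this
protocol's duty cycle), so temporal-mean scaling would bias every recovered
amplitude upward; intercept scaling makes noise-free recovery exact and
leaves t statistics unchanged.

Run-level contrast maps are combined within subject by fixed-effects
inverse-variance weighting (effects weighted by precision, degrees of
freedom summed).

# Nuisance PCA and component-count selection

White-matter and CSF masks are eroded with a 3 mm cubic kernel — 3 x 3 x 3
voxels on the 1.5 mm grid, reading "3 mm" as the center-to-center span
(the alternative 2-voxel reading is available via `kernel_vox`). Voxel time
series inside each eroded mask are centered and their top principal
component time courses (left singular vectors; orthonormal, ordered by
explained variance) enter that run's design matrix as covariates of no
interest. PCs are computed per run from the unsmoothed data (smoothing
mixes gray-matter signal into the compartments) and enter only that run's
model; the source analysis does not state whether components were pooled
across runs, and per-run entry respects the run-wise drift structure.

The number of components per compartment is chosen per subject by
maximizing the whole-brain peak t of the subject-level Sound-vs-Silence
map over a grid of `(k_white, k_csf)` pairs, ties broken toward fewer
components (smallest total, then smallest `k_white`). The objective is
deliberately the statistic being reported — a circular criterion inherited
from the study design; the option exists precisely so it can be disabled
(`optimize = FALSE` with fixed counts) when that circularity is a concern.
Whether the original analysis scored run-level or subject-level maps is
unstated; subject-level is used here, flagged as a convention.

# Group models and random-field inference

* **Fixed effects:** inverse-variance combination across subjects
  (generalizes to the sampled animals only).
* **Random effects:** one-sample analysis of subject-level effect maps,
  `t = mean / (sd/sqrt(n))`, `df = n − 1`, requiring at least 3 subjects.
  Voxels with zero between-subject variance are capped at a large finite t
  with a warning. No between/within variance-ratio regularization is
  applied by default (the source does not state whether it was used).

Family-wise control uses Gaussian-random-field theory. Field smoothness
(FWHM per axis) is estimated from the lag-1 spatial autocorrelation of
standardized residual images under a Gaussian autocorrelation model, or
declared from the applied kernel. Search-region resel counts use lattice
edge/face/cube counting with the top-order count taken as
`voxel volume / prod(FWHM)` (so 1000 voxels of 1.5 mm at 3 mm FWHM give
R3 = 125). The peak threshold is the root of
`sum_d R_d * rho_d(t) = alpha` over the Euler-characteristic densities of a
t field (dimensions 0–3; Gaussian limit available and used for
cluster-forming quantiles), found by locating the upper-tail crossing on a
coarse grid and refining with `uniroot`.

Cluster-size correction forms clusters at the upper-tail quantile of the
cluster-forming probability (0.001 in the Gaussian limit gives the
threshold t = 3.09), labels them by face connectivity (6; 26 available),
and computes the minimum significant extent from the standard GRF
cluster-size approximation: expected cluster count from the EC, expected
suprathreshold volume from the tail probability, and
`P(extent >= k) = exp(-beta k^{2/3})`. A cluster survives by extent or by
containing a voxel above the peak threshold. The "thresholded at p < 0.05"
map convention is implemented as: cluster-forming p = 0.001, family-wise
alpha = 0.05, both configurable.

**Calibration findings worth knowing.** On null simulations the
random-effects voxelwise type-I rate sits at its nominal value. The peak
threshold controls family-wise error as designed, with a caveat the
vignette states because the tests measure it: the EC threshold is derived
for continuous fields, and on fields sampled at 2 voxels per FWHM (the
acquisition regime: 3 mm smoothing on a 1.5 mm grid) the lattice maximum
underestimates the continuous maximum, making empirical FWE conservative
(≈ 0.015 at nominal 0.05). Sampled at 6 voxels per FWHM the empirical FWE
is ≈ 0.05. The calibration suite therefore validates the threshold on
adequately-sampled fields (36³ box cropped from a padded stationary field,
9 mm FWHM) and the conservatism at acquisition resolution errs on the safe
side for inference.

# Jackknife run selection

For each subject the whole-brain maximum t of the Macaque-vs-NonVocal
contrast is computed from all runs (`T_all`) and with each run left out
(`T_minus_r`), using exactly `n + 1` subject-level combinations. A run is
kept iff `T_minus_r < T_all` — removal lowered the maximum, so the run
contributed positively. The inequality is strict, following the rule's
literal statement; a run with zero influence (e.g. an exact duplicate with
infinite variance) produces `T_minus_r = T_all` and is dropped. No
topographical constraint is applied beyond the configured whole-brain mask
(phantom gray matter plus named regions by default). Selection is a single
pass (no iteration), and group maps for the selected contrast are then
recomputed from the kept runs.

# ROI statistics

Spherical ROIs use the voxel-center inclusion rule: all voxels whose
centers lie within `diameter/2` of the center voxel's center. At the
study's 4.5 mm diameter on the 1.5 mm grid this gives exactly 19 voxels.
A1 ROIs are per-subject intersections of the atlas field with the
subject's significant Sound-vs-Silence mask; IC spheres sit on the
random-effects Sound-vs-Silence peak, F5/pMTG spheres on the fixed-effects
Macaque-vs-NonVocal peaks (peak search restricted to the corresponding
phantom label so maxima cannot drift to unrelated regions), and the
aTVA-like sphere at its configured phantom center (its coordinates came
from a separate awake study and are not recoverable from these data).
Bilateral regions are stored and reported per hemisphere.

Profiles extract, per subject, the mean t over ROI voxels for each of the
8 subcategory-vs-silence contrasts (the aggregation statistic is not stated
in the source; mean is the default, peak available), then report the
across-subject mean with the standard error of the mean.

# Numerical choices and degenerate inputs

* Smoothing uses a separable Gaussian whose truncated kernel matrix is made
  doubly stochastic by symmetric (Sinkhorn) renormalization at the volume
  boundary, so constant images and each volume's mean are both preserved
  exactly; simple sample-reflection can only preserve one of the two. A
  periodic ("wrap") variant generates stationary noise fields for
  calibration.
* Convolution grid: 10 ms (five-fold margin on the 50 ms ISI); regressor
  read-off by linear interpolation.
* AR coefficients are clipped to [−0.99, 0.99] and binned at 0.01 for
  whitening.
* `fwhm = 0` smoothing is the identity; an empty eroded mask is legal and
  warns; a t map entirely below the cluster-forming threshold returns an
  empty, valid cluster table; single-run subjects skip the jackknife with a
  warning; a subject retaining zero runs is excluded from group maps with a
  warning.
* Test problem sizes: phantoms of 16³–24³ voxels, cohorts of 2–3 subjects
  with 2–4 runs for end-to-end checks, 500-replicate null calibrations on
  320–46,656-voxel fields, 20–40 replicate recovery and selection studies.
  These sizes were chosen so the full suite characterizes every stage's
  statistical behaviour while remaining routinely runnable.

# Known limitations

* The GRF machinery covers 3-D volumes only (no surface/2-D manifold
  inference) and offers no FDR or permutation alternative.
* The response function is a convention; voxelwise or subject-specific
  hemodynamic estimation is out of scope.
* The component-count objective is circular by design (see above).
* Resel counting follows the voxel-count convention for the top order;
  lower orders use lattice counts. For very small or very sparse masks the
  EC approximation degrades, and thresholds at coarse smoothness are
  conservative as measured above.
* The generator's idealizations listed earlier bound what green tests imply
  about real acquisitions.
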