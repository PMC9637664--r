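---
title: "Quantifying pulmonary perfusion defects from DCE-MRI: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying pulmonary perfusion defects from DCE-MRI: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Dynamic contrast-enhanced (DCE) MRI of the lung records signal enhancement
during the first pass of a contrast bolus. Indicator-dilution theory relates
the tissue enhancement $C_v(t)$ of voxel $v$ to the arterial input function
(AIF) $a(t)$ measured in the pulmonary artery through the residue function
$R_v(t)$:

$$ C_v(t) = \int_0^t a(\tau)\, R_v(t - \tau)\, d\tau . $$

Pulmonary blood flow (PBF) is the maximum of $R_v$, pulmonary blood volume
(PBV) its time integral, and both are summarized for the whole lung as the
median over lung voxels. These absolute metrics are notoriously variable
between scans: errors that act on the whole scan at once — above all an
inconsistent underestimation of the AIF peak caused by temporal
undersampling of the bolus — rescale the entire residue field of a scan by
a common factor.

The perfusion defect percentage (QDP) sidesteps exactly this error class.
Voxels are clustered *relative to each other* within a scan: the residue
map at the scan-level time of maximum lung enhancement (the "Rmax map") is
median-filtered and split into three classes (poorly perfused / well
perfused / vessels) by two-threshold Otsu clustering of its histogram. QDP
is the poorly-perfused voxel count divided by the lung volume. Because
histogram thresholds are derived from the data themselves, a global
rescaling of the map moves the thresholds along with the values and leaves
the classification unchanged — QDP is exactly scale-invariant, and this
package asserts that property to machine precision in its test suite.

## Pipeline

`run_visit()` chains the stages; each is exported on its own.

1. **Quality control** (`qc_exam()`): peak mean lung enhancement over
   baseline noise below a CNR of 5 fails the exam (insufficient
   enhancement); an enhancement peak inside the pre-contrast block or at
   the last frame fails it (bolus mistiming); per-frame artifact scores —
   deviation of the lung-edge signal profile from its temporal-neighbor
   median — flag corrupted frames, and an exam with more than 25% flagged
   frames fails (breathing artifacts). These thresholds are operational
   surrogates for a visual review and are configurable; `exclude_frames()`
   supports the manual removal of corrupted acquisitions before or after
   the bolus passage, with the automated score as advisory input.
2. **Subtraction** (`compute_subtraction()`): the mean of the first two
   pre-contrast frames is subtracted from every frame. Negative values are
   retained; pre-contrast noise is symmetric about zero.
3. **AIF detection** (`detect_aif()`): voxels in the search region (an
   arterial mask, or simply all extrapulmonary voxels) are ranked by peak
   enhancement; candidates whose peak frame strays more than one frame from
   the candidate-set mode are discarded (ties resolved toward the earlier
   frame, preferring first-pass over late-enhancing populations); the AIF
   is the mean of the top ten remaining curves.
4. **Deconvolution** (`tsvd_deconvolve()`): the discrete convolution
   operator $A_{ij} = \Delta t\, a_{i-j+1}$ is inverted by truncated SVD,
   discarding singular values below 20% of the largest. The truncation
   fraction is the standard regularization of indicator-dilution
   deconvolution; 0.2 is established practice and configurable. The Rmax
   map is $R_v$ evaluated at the scan-level frame of maximum mean lung
   enhancement (a per-voxel-maximum mode exists for sensitivity analyses).
5. **Maps** (`compute_pbf()`, `compute_pbv()`): PBF is the per-voxel
   maximum of $R_v(t)$, floored at zero; PBV is the per-voxel time integral.
   Residue units are 1/s; the constants 6000 and 100 convert to
   ml/100ml/min and ml/100ml on a relative calibration (absolute
   calibration via relaxivity is out of scope).
6. **Clustering** (`median_filter_rmax()`, `otsu_two_thresholds()`,
   `gravity_adapt_threshold()`, `classify_and_qdp()`): slice-wise 5×5
   mask-aware median filtering, two-threshold Otsu on a 256-bin histogram
   of the masked values, per-slice adaptation of the lower threshold for
   the gravity-direction perfusion gradient, then classification. Voxels
   below the (per-slice) lower threshold are the defect class; vessels
   remain in the QDP denominator, which is the full segmented lung volume.
7. **Lung segmentation** (`region_grow()`): seeded region growing on the
   morphological volume with a radius-1 closing. Default seeds are the
   darkest voxels of the left and right volume halves (air-filled lung is
   dark on T1 gradient echo); the default window upper bound is a
   single-threshold Otsu split of the intensity histogram. Registration
   between morphological and DCE grids is out of scope (the phantom
   provides aligned volumes); `resample_mask_nn()` is a nearest-neighbour
   hook for grids that differ only in sampling.

## Numerical choices worth knowing

**PBV uses the trapezoidal rule.** At a frame interval of 1.5 s and transit
times of 5–8 s, a left-rectangle sum over a decaying residue function
overestimates its integral by $\approx \Delta t / (2\,\mathrm{MTT})$, i.e.
9–16% — far larger than the deconvolution's own integral error (about 2%).
The trapezoidal rule restores the tracer-kinetic identity
$\mathrm{PBV} = \mathrm{PBF} \cdot \mathrm{MTT}/60$ to $O(\Delta t^2)$.
Negative residue samples are kept in the integral (preserving unbiasedness
under noise) and the final map is floored at zero; the PBF map floors each
voxel maximum at zero.

**Gravity adaptation references the well-perfused voxels.** The per-slice
threshold is the global Otsu threshold scaled by the ratio of the slice
median to the whole-lung median *over voxels at or above the global
threshold*, clamped to [0.5, 2]. Taking the median over all lung voxels
instead would let the ratio track the spatial distribution of defects
rather than gravity: wherever defects concentrate in a few slices, the
defect-free slices receive inflated thresholds and whole slices get
mislabeled (we measured tens of percentage points of QDP error at high
defect burden). Restricting to the well-perfused population isolates the
gravity shift of the normal mode, which is what the adaptation is meant to
capture.

**Otsu ties.** With empty histogram bins between well-separated clusters,
many threshold pairs attain the identical between-class variance. The
search breaks ties toward the smaller pair; the test suite therefore
verifies the *attained criterion* against an exhaustive search rather than
the threshold pair itself.

**Wilcoxon signed-rank.** Zero differences are dropped (the classic
policy) and counted. For up to 25 retained pairs the exact null
distribution of the positive-rank sum is built by generating-function
convolution over the (possibly tied, average) ranks — tied ranks therefore
still get exact p-values, which `stats::wilcox.test()` refuses; the
tie-free case is cross-checked against it in the tests. Larger samples use
the tie-corrected normal approximation without continuity correction.

**MID multiplier.** The minimal important difference is reported as
$1 \times \mathrm{SEM}$ with $\mathrm{SEM} = \sqrt{MS_{error}}$ from the
two-way repeated-measures ANOVA (subject + visit); the two-occasion
identity $\mathrm{SEM} = \mathrm{SD}_{diff}/\sqrt{2}$ is asserted to
1e-10 in the tests. A multiplier of $1.96\sqrt{2}$ yields the smallest
detectable change instead. Percent normalizations use the median pooled
over all $2n$ observations.

**Comparator clustering rules.** The k-means comparator runs 1-D 3-cluster
k-means with 50 random restarts under an internally fixed seed (restart
averaging stands in for k-means++ initialization, which base R does not
provide); the defect class is the lowest-center cluster. The percentile
comparator thresholds at the 20th percentile of the masked histogram — an
interpretation, recorded as such, with the consequence that its QDP is 20%
by construction on continuous data: perfectly stable and completely
insensitive to the true defect extent, which is exactly why it is a useful
negative control.

**Pearson–Filon test.** The classical (1898) statistic for two dependent
correlations sharing one variable, computed here on rank-transformed data
for consistency with the Spearman correlations it compares. Its finite-n
calibration is validated by a seeded Monte-Carlo null simulation (10,000
trivariate-normal draws at n = 27) in the acceptance tests.

## The phantom: what it emulates, and what it does not

`phantom_spec()` / `make_phantom_truth()` / `synthesize_visit()` build a
4D digital thorax: two ellipsoidal lungs inside bright soft tissue (tight
field of view, no exterior air — which keeps darkest-voxel seeding
well-posed), a mediastinal arterial block carrying the ground-truth AIF,
randomly grown connected defect blobs (region growth to a target voxel
count; focal defects rather than scattered voxels), intrapulmonary vessel
blobs, and exponential residue functions
$R_v(t) = (\mathrm{PBF}_v/6000)\,e^{-t/\mathrm{MTT}_v}$ forward-convolved
with a gamma-variate AIF.

Defaults define the simulated study conditions: a 64×64×24 voxel grid at
3×3×6 mm, 40 frames at $\Delta t = 1.5$ s (a 60 s window, at least five
transit times), four pre-contrast frames, bolus onset 4.5 s with shape
$\alpha = 2$, $\beta = 2$ s (first-pass width ≈ 7 s, an early
pulmonary-artery bolus) and a 10% recirculation bump after 15 s; normal
PBF 60 ml/100ml/min with MTT 5 s (PBV 5 ml/100ml — consistent with
whole-lung medians reported for patient cohorts, which imply a whole-lung
MTT near 5 s), defects at 15% of normal flow with MTT 8 s, vessels as a
high-flow dispersed arterial compartment at 4× normal flow, a linear
gravity gradient of 1.5%/slice, Gaussian noise at CNR 20 (peak normal-lung
enhancement over noise SD), and a defect extent of 30% of the lung in
three connected blobs. A tissue arrival delay is deliberately absent:
plain truncated-SVD deconvolution is delay-sensitive, and delay-insensitive
(block-circulant) variants are out of scope, so the phantom matches the
model class the deconvolution assumes.

Two error mechanisms connect the two visits of a subject. A global gain
(`visit_scale_error`) multiplies the entire visit-2 signal; because the
AIF is re-detected per scan, this cancels identically in the deconvolution
— a property the tests assert — so it probes the pipeline's intrinsic
normalization. The per-scan arterial-amplitude error (`aif_scale_error`,
drawn from U[0.8, 1.2] in the cohort sampler) scales only the measured
arterial (and vessel) signal, leaving tissue untouched: the deconvolved
residue field of that scan is then off by the inverse factor, exactly the
"whole residue function underestimated by a common factor" mechanism that
makes PBF and PBV irreproducible while QDP is untouched. Breathing
artifacts are emulated by a 2-voxel in-plane shift plus a 1-voxel Gaussian
blur on listed frames — coarse, but sufficient to trigger frame-level QC.

What the phantom does *not* emulate: MR signal equations and sequence
physics, contrast-agent nonlinearity, per-voxel transit delays and
dispersion, cardiac pulsation, realistic defect morphology distributions
(the blob model is a stand-in, not a fit to patient data), respiratory
motion beyond the frame-corruption surrogate, and registration error
between morphological and dynamic volumes. Passing phantom tests therefore
demonstrates the correctness and internal robustness of the computation —
not clinical performance on patient data.

## Problem sizes and determinism

The validation suite runs the full pipeline on the default 64×64×24×40
grid: sixty phantoms across defect fractions of 10/30/50% at CNR 20 for
defect-recovery accuracy, a 20-phantom fraction sweep for monotonicity,
and a 20-subject two-visit cohort for the agreement ordering; unit tests
use a 32×32×12 grid. Every stochastic step is seeded: phantom geometry and
noise from `rng_seed` (visit 2 offsets the noise stream only), cohorts
from a single master seed, the k-means comparator internally (it saves and
restores the caller's RNG state). Identical configuration and seeds
reproduce every table bit-identically.

## Known limitations

- The scan-level Rmax frame samples all residue functions on their decay;
  voxel contrast between perfusion classes is therefore smaller than at
  the per-voxel residue peak, and QDP accuracy degrades below roughly
  CNR 10 under the default geometry.
- Truncated-SVD deconvolution underestimates PBF by roughly 10–15% at the
  default truncation (a well-known bias); PBV is recovered much more
  accurately. Whole-scan comparisons are unaffected, absolute values carry
  the bias.
- The per-slice gravity adaptation assumes at least some well-perfused
  lung per slice; slices that are entirely defect fall back to the global
  threshold and their defect extent is measured against it.
- The exam-QC thresholds are surrogates chosen for the phantom's noise
  model; on patient data they would need recalibration against a visual
  standard.
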