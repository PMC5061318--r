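---
title: "Methods: multi-pose larval brain imaging analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-pose larval brain imaging analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multipose)
```

# The problem

High-content screening in larval zebrafish requires imaging a specific
anatomical region — here the dopaminergic (DA) neuron cluster in the
forebrain — at cellular resolution, in 96-well plates, one larva per well.
An anesthetized larva settles in an essentially random pose; the brain is
only visible when the dorsal side faces the objective, because the heavily
pigmented eyes otherwise occlude it. The multi-pose strategy images each
well several times, re-suspending the larva between acquisitions, so that
at least one dorsal-side-down frame is obtained with high probability: with
a per-cycle dorsal rate $p$ and $c$ independent cycles, the chance of at
least one usable pose is $1 - (1-p)^c$ (about 99% for $p = 0.688$, the
round-bottom-plate rate, and $c = 4$).

This package implements the downstream analysis: finding the brain in each
acquisition, scoring neuronal health against an idealized template, and
quantifying the quality of the resulting assay. It also ships a synthetic
acquisition generator so that every stage is testable without instrument
data.

# Pipeline

Each pose consists of one bright-field frame and a seven-slice fluorescence
z-stack (slices 100 µm apart). Localization proceeds as:

1. **Maximum projection** of the fluorescence stack (`max_project()`).
2. **Head detection** on the first, most defocused z-slice with a
   gradient-voting circular Hough transform searching diameters 80–150 px
   (`detect_head()`). Edge pixels vote for centres along their gradient
   direction over the radius range; the accumulator peak is refined to the
   vote centroid. A second validation stage walks the strongest accumulator
   peaks and keeps the best-supported one, where support is the fraction of
   the candidate circle's perimeter carrying an inward-pointing gradient
   above the image's noise floor. This rejects vote pile-ups produced by
   blobs outside the radius range and by structure-free images.
3. **Orientation normalization** (`orient_head_up()`): the projection is
   binarized with Otsu's threshold and the principal axis of the foreground
   coordinates gives the rostro-caudal axis; both channels are rotated so
   this axis is vertical. Two robustness details matter in practice. When a
   handful of very bright somata dominate the histogram, the first Otsu
   split can isolate them alone — far too little area to define a body
   axis — so the threshold is recomputed on the sub-threshold intensities,
   recovering the fish-versus-background separation. The 180° ambiguity is
   resolved by requiring the detected head to lie *rostral of the
   foreground centroid* (the yolk and trunk pull the centroid caudally);
   comparing against the frame centre instead fails whenever the larva is
   off-centre.
4. **Eye detection** (`detect_eyes()`): the bright-field is halved in size
   and matched-filtered with a zero-mean dark-oval kernel of 60 × 90 px;
   the response is Otsu-thresholded and the centroids of the two largest
   regions are the eyes. Poses with fewer than two regions or an eye
   separation outside 40–120 half-size px (a plausibility gate against
   yolk and frame-edge artifacts) are rejected — this is what makes
   lateral poses fail loudly rather than mis-localize.
5. **Brain landmarking** (`locate_brain_center()`): the brain centre is
   35 half-size px caudal of the eye-to-eye midpoint, scaled ×2 into
   full-size coordinates.
6. **Cropping** (`crop_brain()`): a 190-row × 220-column crop around the
   brain centre, with the Otsu-dark class of the bright-field as an eye
   mask. Out-of-frame area is zero-padded and flagged.

Coordinates are 0-based `(row, col)` with the origin top-left; "head-up"
means rostral toward row 0; rotation angles follow `transform_points()`.
The crop is 190 rows (rostro-caudal) × 220 columns (left-right).

Across poses of a well, the successful pose with the highest total
fluorescence inside its crop is selected automatically (ties go to the
earlier cycle); a manual-override file replaces the interactive best-pose
review so batch runs are reproducible (`select_best_pose()`,
`read_manual_poses()`).

# Scoring

The eye mask is applied first (`mask_eyes()`), removing eye
autofluorescence. For segmentation, a Gaussian with a full width at half
maximum of 12 px smooths the image and the smoothed image is subtracted
from the original (`subtract_local_background()`), removing broad
background while retaining neuron-scale structure (a single-pixel impulse
keeps more than 99% of its height; objects comparable to the kernel keep
roughly half). Neurons are segmented at 5 × the two-class Otsu threshold of
the subtracted image, keeping connected components with equivalent-circle
diameters of 5–20 px (`segment_neurons()`).

Two implementation details of that threshold deserve explanation. First,
our Otsu (`otsu_threshold()`) resolves plateaus in the between-class
variance at the *smallest* maximizing bin (the scikit-image convention).
When the histogram has an empty gap between background and objects — the
case for hard-edged, noise-free fixtures — the variance is constant across
the gap, and this tie-break anchors the threshold just above the
background class, which the ×5 correction factor then calibrates upward.
Second, on images whose histograms are genuinely bimodal with a continuum
of edge-ramp pixels in between (any optically blurred acquisition), the
Otsu optimum sits at roughly 0.45 × the bright-class scale, and five times
that exceeds every object pixel: the correction factor is then a very
conservative setting that detects only the brightest somata, or none. This
is a real property of the threshold rule itself, not an artifact of this
implementation; it is why the Brain Health Score below — which does not
depend on segmentation at all — is the assay's readout, with object
counts and features reported as supplementary measurements.

The **Brain Health Score** is

$$\mathrm{BHS} = \log_2 \sum_{i,j} I_{ij} M_{ij}$$

where $I$ is the eye-masked (not background-subtracted) brain crop and $M$
an idealized healthy-brain template with values in $[0,1]$. Although
sometimes described as a covariance, the formula is an uncentered inner
product and is implemented exactly as defined. Consequences used by the
test suite: scaling the image by $k$ shifts the score by $\log_2 k$
exactly; a uniform image factorizes to $\log_2 \sum M$; a zero image is
recorded as missing (flag `zero_overlap`) rather than $-\infty$, keeping
the robust statistics downstream well defined. The choice of the
*unsubtracted* masked crop as $I$ is configurable (`default_config()`
key `scoring$bhs_input`), since the alternative reading is defensible.

The **template** (`build_template()`) averages healthy crops after rigid
registration (rotation + translation, normalized cross-correlation with a
multi-start search over ±15°), subtracts the smooth background with a
rolling ball of radius 150 px — implemented as a grayscale morphological
opening with a disc structuring element, the standard equivalent — blurs
with a Gaussian of σ = 7 px, and rescales to $[0,1]$. We average the
*eye-masked* crops: the sources are masked at the same pixels as every
image later scored against the template, so eye-autofluorescence ridges
never enter $M$, and the masking is neutral for BHS because $I$ is zero
there anyway. Building a template from copies of one crop equals
processing that crop alone, which pins down the registration and rescale
conventions.

# Screening statistics

For positive (vehicle) and negative (ablation) control arms:

* `z_prime()`: $Z' = 1 - 3(\sigma_+ + \sigma_-)/|\mu_+ - \mu_-|$; with
  `robust = TRUE` the means and SDs are replaced by medians and *raw*
  median absolute deviations. The 1.4826 normal-consistency factor is
  **not** inserted into robust $Z'$ — the two conventions disagree, and we
  follow the formula with MADs used directly — so on normal data robust
  $Z'$ sits below classic $Z'$ by exactly that factor on the dispersion
  term (a relationship the tests verify).
* `ssmd_star()`: $(\tilde X_+ - \tilde X_-) / (1.4826\sqrt{\tilde s_+^2 +
  \tilde s_-^2})$ with raw MADs $\tilde s$, the 1.4826 exactly where the
  formula places it. For unit-SD normal arms separated by $\Delta$ this
  converges to $\Delta/\sqrt2$.
* `required_sample_size()`: $n = \lceil 2 (Z_\alpha + Z_{1-\beta})^2
  \sigma^2 / \Delta^2 \rceil$, with $Z_\alpha$ the *two-sided* 0.5%
  false-positive quantile (2.81; the one-sided reading gives 2.58 and is
  inconsistent with the 2.81 the assay design uses) and $Z_{1-\beta} = 1.28$ for a 10%
  false-negative rate. The pooled SD is $\sqrt{(s_+^2 + s_-^2)/2}$ and
  the sample size is rounded up. `normalized_effect()` divides an effect
  by the full control separation.
* `bootstrap_group_averaging()`: per replicate, each arm is resampled with
  replacement to its original size, randomly partitioned into groups of
  size $g$ (remainder observations dropped within that replicate), group
  means are formed, and the three metrics are computed on the means; means
  across 1000 replicates are reported per $g \in 1..5$. Degenerate
  replicates (tied resamples with zero spread) are dropped from the
  average. Averaging shrinks the dispersion terms by roughly $\sqrt g$,
  so SSMD* grows accordingly.
* `chi_squared_2x2()` (Pearson, no continuity correction) and
  `one_way_anova()` wrap the standard tests for the posing-rate
  comparison and dose-response analysis.

# The synthetic generator

`render_pose()` draws a stylized larva: in bright-field, a bright
transmitted-light background (3000 counts), a nearly transparent body
(2800 counts — the larvae are PTU-treated, so the body is unpigmented) and
near-black eye ellipses (150 counts, 90 × 130 px, separated by 160 px); in
fluorescence, a camera offset, a faint body, a smooth dim autofluorescence
texture over the tissue, a diffuse head blob (110 px diameter), eye
autofluorescence (the reason eye masking exists), a caudal yolk blob, and
the neuron cluster: 30 disks of 8–14 px diameter, placed without overlap
inside a 65 px-radius disc centred 70 px caudal of the eye midline,
avoiding the dorsal eye ellipses (in the dorsal view the DA cluster is
unobstructed — the premise of the assay). Ablation removes each neuron
independently with the given probability. Defocus is modelled as a
Gaussian blur whose σ grows linearly with the slice distance from focus
(1.5 px + 2.5 px per slice) — the simplest monotone defocus proxy —
followed by Gaussian camera noise (SD 50 counts) and 16-bit quantization.
Geometry defaults are sized so the pipeline's fixed constants apply: the
head blob and the defocused cluster fall in the 80–150 px Hough range and
the half-size eyes (≈45 × 65 px) respond to the 60 × 90 px oval filter.

Intensity scales were chosen to mimic a 500 ms exposure of a bright
mCherry line: neuron amplitude 8000 counts (jittered ±20% per neuron, and
log-normally by ~10% per larva), tissue texture ~120 counts, yolk 1200
counts (log-normal ~15% per larva). The neuron-to-texture contrast
matters: the ×5 segmentation threshold sits between the texture
fluctuation edge and the neuron cores only when somata are bright
relative to the diffuse background, as they are in the real assay.

`simulate_well()` redraws orientation (dorsal with probability 0.688, the
round-bottom rate; the remainder split 9:1 between lateral and
not-imageable), axis angle (uniform) and head position (within 60 px of
the well centre — round-bottom wells guide the head to the centre) per
cycle, independently. The observed cumulative posing curve suggests
re-posing outcomes are not independent across cycles in reality; we do not
model that correlation, so the generator reproduces the binomial
complement $1-(1-p)^c$ exactly rather than the empirical curve.
`simulate_plate()` writes 16-bit TIFFs plus a CSV manifest and ground
truth, reproducibly per seed. `synthetic_crop()` stamps hard-edged disks
at crop scale — the noise-free fixture on which segmentation counts are
provably exact.

What the generator does *not* emulate: optical aberrations of round-bottom
wells, pigmentation variability, multi-larva wells, correlated re-posing,
or realistic neuropil morphology. Passing tests on synthetic plates
therefore demonstrate the pipeline's geometric and statistical
correctness, not its robustness to every real-world imaging artifact.

# Numerical choices and degenerate inputs

* Rotation uses bilinear interpolation with a constant fill equal to the
  image median, so rotation never introduces dark eye-like corners.
* The ×0.5 resize is bilinear; the brain centre is scaled ×2 back without
  half-pixel correction (sub-pixel conventions are dwarfed by the 5–10 px
  acceptance tolerances).
* Otsu thresholds are computed on 256-bin histograms; large images are
  subsampled 4:1 for thresholding (statistically identical, measurably
  faster).
* `brain_health_score()` of an all-zero image, `z_prime()` with equal
  locations, `ssmd_star()` with both MADs zero, and empty template input
  are hard errors or flagged missing values, never silent numbers.
* Wells where every pose fails localization become "unusable" records;
  every well appears exactly once in the scores or the unusable list.

# Problem sizes used in the tests

The bundled validation uses full-frame (1040 × 1392) renders throughout:
200 random dorsal larvae for the localization-recovery study, a full
44 + 44 two-arm plate (one cycle, all-dorsal, ablation fraction 0.9 in the
treatment arm) for the end-to-end screen, 1000-replicate bootstraps for
the averaging curves, and 2 × 10⁵-sample arms for the large-sample SSMD*
limit. The acceptance script repeats the same computations with a
100-larva recovery study. These sizes give Monte-Carlo error comfortably
below the tolerances being checked.

# Known limitations

* The segmentation correction factor of 5 is conservative on blurred
  renders (see above); object counts on full-optics images undercount by
  design of the threshold rule.
* Registration inside `build_template()` is integer-pixel in translation
  and 1°-grid in rotation — adequate because localization already aligns
  crops to a few pixels.
* The Hough stage assumes one larva per well; multi-larva wells are out
  of scope.
* BHS compares against a single template; multi-parametric classifiers
  over the exported features are deliberately not implemented.
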