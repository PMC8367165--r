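---
title: "Wound image quality control: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Wound image quality control: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(woundqc)
```

## The problem

Patients who photograph their own wounds at home — for example digital
ulcers on the fingers in systemic sclerosis — produce images of very uneven
quality. Two failure modes dominate: the photograph is out of focus, and the
color reference sticker (a square 30 x 30 mm marker with 36 printed color
patches, placed beside the wound for color and size calibration) is missing
or too small in the frame. Both can be checked *at acquisition time*, so the
patient can be asked to retake the image while they are still holding the
camera. `woundqc` implements that quality gate and the analysis layer used
to evaluate it in a two-arm study (a "feedback" app with the gate versus a
"basic" app without it).

## The sharpness measure

Sharpness is scored as the **variance of the Laplacian**. The discrete
Laplacian used is the 4-connected stencil

$$\nabla^2 I \approx I_{x-1,y} + I_{x+1,y} + I_{x,y-1} + I_{x,y+1} - 4\,I_{x,y}$$

with replicate (edge-clamp) border handling. It is a second-derivative
operator: it responds to rapid intensity changes (edges, texture) and
annihilates constant and linearly varying regions. Blur attenuates exactly
the high spatial frequencies the operator passes, so the *population
variance* of the response over a region is a focus measure: high when fine
detail is present, falling monotonically as Gaussian blur widens.

Design choices a user should know, with the reasons they were made:

* **Grayscale conversion** uses ITU-R BT.601 luma (0.299, 0.587, 0.114),
  the default of the common imaging libraries, so scores are comparable
  across toolchains.
* **Population variance** (divide by $N$), not the $N-1$ sample variance;
  with thousands of region pixels the difference is negligible, but the
  convention is documented and fixed.
* **No resizing** before scoring. The variance of the Laplacian is
  resolution-dependent, so scores are only comparable between images of the
  same scale; scoring at native resolution is the contract.
* The score is invariant to constant intensity offsets (illumination
  shifts) and scales quadratically with intensity gain.

Because image content drives the measure, the score is computed over the
**color checker region of interest** (CCS, color checker sharpness): the
sticker's printed content is constant across patients and assessments,
making scores comparable where whole-image scores would not be. The scored
quadrilateral is shrunk inward by 2 px: the sticker's outermost edge carries
Laplacian energy from contrast against the background, which reflects the
scene rather than focus and makes the score needlessly sensitive to
one-pixel localization differences.

## Sticker detection

The sticker is found by rectangular morphology:

1. A foreground map flags pixels that stand out from the dominant
   background either in luma (|difference from the image median| > 20) or in
   chroma (max − min channel > 30). The median is a robust background
   estimate as long as the background covers most of the frame, which the
   imaging-holder geometry guarantees.
2. Small gaps are closed morphologically (disc of diameter 5) and connected
   components are labelled.
3. Each component of at least 25 px is fitted with its minimum-area
   enclosing rectangle (rotating calipers over the convex hull).
   Candidates must fill that rectangle (**rectangularity**
   component-area / rectangle-area ≥ 0.85 — an ellipse fills only
   $\pi/4 \approx 0.785$, which is what separates the sticker from rounded
   anatomy) and be near-square (aspect ratio ≤ 1.3 by default).
4. The rectangle must exceed the configured **size threshold**
   (`min_area_fraction`, default 0.02 of the frame): a sticker too small in
   the field of view is useless for calibration and indicates a wrong
   camera distance. A candidate failing *only* this test is reported
   upstream as `checker_too_small`, distinct from `checker_not_found`.
5. Optionally (`grid_check`, on by default) the 6 x 6 patch structure is
   verified by sampling the 36 patch-center colors through a bilinear map
   of the unit square onto the candidate quadrilateral and requiring their
   mean pairwise RGB distance to exceed 30. This tests structure, never
   specific colors.

Ties among passing candidates go to the largest area, then the top-left
corner position, so detection is fully deterministic. Corners are reported
clockwise from top-left in 0-based pixel coordinates.

The thresholds in steps 1–5 are package constants chosen on the synthetic
suite (below) and validated by its recall/false-positive properties; the
size threshold and aspect bound are user-configurable because they encode
acquisition policy rather than algorithm internals.

## The quality gate

`assess_quality()` passes an image exactly when the sticker is detected
and its region sharpness **strictly exceeds** the configured threshold
("exceeding" is read strictly; at the threshold itself the image is
retaken). Failures carry machine-readable reasons: `checker_not_found`,
`checker_too_small`, `blurry`. The default threshold (483) is the frozen
output of `calibrate_sharpness_threshold()`: the midpoint between the
median CCS of 20 unblurred synthetic scenes and the same scenes blurred at
sigma = 4 — a data-driven default, since no published value exists, and
every deployment should recalibrate for its own optics via the same
function. The gate scores the sticker region only; whether the wound itself
is in focus is assumed to follow from the shared focal plane the holder
enforces.

## The synthetic scene generator

No real patient images ship with the package, so every pixel-level claim is
tested against rendered scenes with ground truth that is true by
construction. A scene is: a flat background plate (value 70), an optional
elliptical skin blob with radial shading and a darker wound core, and an
optional square 6 x 6 patch sticker at a specified center, side and
in-plane rotation, followed by Gaussian blur (optical defocus), a constant
illumination offset, and additive Gaussian sensor noise clipped to
[0, 255]. The 36-patch palette is a fixed constant: the 24 classic
photographic calibration colors plus 6 skin and 6 wound shades; the
commercial sticker's exact palette is unpublished, so tests verify patch
*structure*, never colorimetry. Rendering is bit-identical for identical
spec and seed, and changing only the seed changes noise but not geometry.

What the generator deliberately does **not** model: perspective distortion
(only in-plane rotation), specular highlights, shadows, demosaicing or
compression artifacts, and photo-realistic wound appearance. Passing the
detection recall/false-positive suites therefore demonstrates correctness
of the morphology pipeline under controlled degradation, not clinical
performance on real photographs.

`random_scene_spec()` draws poses from the variability left after the
holder fixes distance and lighting: sticker side 90–130 px in a 480 x 360
frame (area fraction 0.047–0.098), rotation ±20°, sticker in the right half
and wound in the left so the two never merge into one component. The
480 x 360 working resolution keeps a full 100-scene suite comfortably fast
while leaving ~15–22 px per patch, the same order as a downscaled phone
preview frame.

## The study metrics layer

* **CCDR** (color checker detection ratio): detected over collected images,
  `n_detected / n_total`. Group CCDR pools counts across patients (it is
  not the mean of per-patient ratios).
* **CCS summaries**: median and quartiles (linear interpolation between
  order statistics, R's default type 7). Both pooled per-image
  distributions and per-patient medians are exposed, since group
  comparisons were made both ways.
* **Usability ratio**: subjectively-usable over labeled images.
* **Compliance**: distinct calendar days with at least one saved image,
  divided by the 16 assigned days, capped at 1 — over-performing patients
  are fully compliant, not more. Days are counted as distinct dates because
  multiplicity within a day is undefined by the protocol.
* **Duration outliers**: values more than 3 *scaled* MADs from the median,
  scaled MAD = 1.4826 x MAD so it estimates the standard deviation under
  normality. With zero MAD (all values equal) only exact-median values
  survive, which is the intended degenerate behavior. The filter is not
  idempotent in general since the median and MAD are recomputed on the
  kept values.
* **Rank-sum test**: pooled midranks; exact distribution when both samples
  are below 50 and tie-free (the p then equals the permutation p), normal
  approximation with tie and continuity correction otherwise — mirroring
  standard implementations. The normal approximation alone misses the
  exact p by up to ~0.04 at $n = 3$, which is why the exact branch exists.
  The reported statistic is the corrected z-score in both cases.
* **Duration trend**: ordinary least squares of duration on assessment
  index, one duration per assessment, after per-patient outlier filtering.

## The cohort generator

`cohort_spec()` defaults encode the study's operating point: 8 feedback
and 7 basic patients, 16 assigned assessment days (every third day over 8
weeks), 2 images per performed day with a 0.2 skip probability (≈ 25.6
images per patient, matching the observed 24.9/26.1), detection
probabilities 191/199 and 158/183, usability 180/199 and 155/183, and
log-normal sharpness laws parameterized directly from the printed medians
and quartiles: $\mu = \log m$, $\sigma = \log(q_{75}/q_{25}) / (2 z_{0.75})$,
giving (6.796, 0.253) for the feedback group (median 894, IQR 710–999) and
(6.551, 0.339) for the basic group (median 700, IQR 549–867). The
log-normal was chosen because sharpness is positive and right-skewed; the
study published only medians and quartiles, which this law matches exactly
in expectation. Durations follow 55 − 0.8 · index + N(0, 8²) seconds,
floored at 5 s — an efficiency trend of the plausible sign and a median
below 50 s; the per-assessment data behind the published medians were
never released, so these three constants are the generator's own
assumptions and duration results are illustrative only.

## Numerical and degenerate-input conventions

* Laplacian requires at least 3 x 3 pixels; ROIs must select ≥ 2 pixels.
* Detection failure is a normal `found = FALSE` result, never an error;
  scoring a failed detection *is* an error.
* All operations are pure: identical inputs give identical outputs, and
  the generators take explicit seeds (the caller's RNG state is saved and
  restored).
* Quantiles of a single value collapse to that value; `ccdr` with zero
  images and compliance with zero assigned days are errors, not NaN.

## Problem sizes used by the shipped checks

The test-suite and acceptance-script simulations use 100-scene detection
suites, 20-scene blur ladders at sigma in {0, 0.5, 1, 2, 4}, 100 simulated
cohorts (~400 images each) for the rank-sum power estimate, and 200 random
grids up to 16 x 16 for the convolution oracle — sizes at which the
binomial and permutation bounds quoted in the tests are sound while a full
run stays in the minutes range on one core.

## Known limitations

* The detector assumes one sticker and a mostly-uniform background; it is
  not a general chart detector and does not rectify perspective.
* CCS values are comparable only within one resolution and optical setup;
  the default pass threshold must be recalibrated for any new device.
* Synthetic cohorts reproduce the study's *summary* distributions, not
  patient-level correlation structure (a patient's images are independent
  draws given the group).
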