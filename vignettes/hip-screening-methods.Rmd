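---
title: "Methods: synthetic Graf-plane phantoms, landmark segmentation and decision support"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: synthetic Graf-plane phantoms, landmark segmentation and decision support}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipscreen)
```

This vignette is the package's account of its own modeling choices: what
each stage assumes, which parameters matter, where the design was
genuinely open and what was decided, and what the synthetic evaluation
does and does not demonstrate about clinical data.

## The screening problem

Graf-method hip ultrasound grades an infant hip from a coronal
standard-plane image. Two indices carry most of the signal: the **alpha
angle** between the iliac baseline and the bony acetabular roof
(≥ 60° normal) and the **femoral head coverage**, the fraction of the
femoral head medial to (covered by) the baseline (≥ 50% normal). The
workflow modeled here replaces single expert-acquired images with a cine
sweep: many frames are acquired while the probe crosses the hip, frames
without complete landmarks are rejected automatically, and the surviving
frames are measured and aggregated into a three-way management
suggestion. This shifts the hard problem — recognizing a valid standard
plane — from the operator to the software, which is what makes screening
by lightly trained primary-care staff plausible at all.

## Coordinate and orientation conventions

One convention is fixed once and used by every module: masks and images
are `(row, col)` matrices, origin top-left; rows increase inferiorly;
columns increase **medially**. The iliac baseline therefore renders
near-vertical and the covered side of the femoral head is toward larger
column indices. For mirrored input the medial direction is a declared
configuration value (`geometry_config(medial = "-col")`), not something
the package guesses from content.

## The phantom generator

`phantom_spec()` fully parameterizes one synthetic hip. The geometry is
analytic: baseline direction `(1, 0)`; roof direction
`(cos α, sin α)` leaving the rim point, so the constructed angle equals
`alpha_true` to machine precision; the head disk center sits at a signed
offset `s` from the baseline along its medial normal, giving the
diameter-fraction coverage `clip((r + s)/(2r), 0, 1)` exactly. The head's
depth below the rim is chosen at render time so the disk always clears
the roof line — this keeps the class-2 boundary a complete circle, which
is what the circle fit assumes.

The corruption model is deliberately simple and controllable rather than
physical:

- **Speckle**: multiplicative unit-mean gamma noise with variance
  `speckle_strength` (default 0.02). Speckle in real ultrasound is
  multiplicative and sub-resolution; a gamma factor reproduces the
  first-order texture without a scatterer simulation.
- **Blur**: isotropic Gaussian of `blur_sigma_px` (default 0.8 px),
  standing in for the system point-spread function.
- **Acoustic shadow**: intensities strictly below a bone stroke in the
  same column are attenuated by `shadow_strength` (default 0.1), the
  dominant artifact under calcified structures.
- **Out-of-plane decay**: within `adequate_band_px` (default 6 px) of the
  standard plane all landmarks render fully; beyond it the femoral head
  disappears and bone echo intensity decays linearly, reaching zero at
  twice the band. This gives the adequacy gate realistic partial frames
  to reject, and makes "adequate" exactly decidable from the construction.

Contrast levels (background 0.35, bone 0.92, head 0.08, stroke width
6 px at the default 192×160 frame) were chosen once to resemble the
schematic appearance of a Graf-plane image — a bright near-straight iliac
echo, an echogenic roof, a hypoechoic head — and are constants of the
generator, not tuning knobs. No deposited clinical images exist for this
pipeline, so phantom realism is bounded by that schematic: the phantoms
have exactly two bright strokes and one dark disk, while real frames
contain labrum, capsule, ossification centers and operator-dependent
gain. Consequences for interpretation are discussed at the end.

`make_dataset()` draws per-subject geometry uniformly from requested
ranges (defaults α ∈ [45, 80]°, coverage ∈ [0.3, 0.85], radius
[20, 28] px, rim jitter ±6 px) and renders a few near-plane frames per
subject under the default corruption — the "low-noise" study condition
used for training and evaluation throughout.

## Segmentation

Inputs are normalized by dividing by the overall mean intensity (the
normalized image has mean exactly 1) and resized bilinearly to a square
network input. Masks are resized nearest-neighbor so labels stay
integral.

The segmenter is a U-Net-style encoder/decoder: per level, two 3×3
same-padded convolutions with ReLU; 2× max pooling between levels;
nearest-neighbor upsampling followed by a 3×3 convolution and skip
concatenation on the way up; a 1×1 convolution to three-class softmax
logits. Weights are Xavier-uniform initialized. Training minimizes a
soft DICE loss averaged over the two **foreground** classes only —
background covers ~95% of pixels and would otherwise swamp the loss —
with smoothing constant ε = 1 px to keep empty classes well-defined. The
optimizer is Adam at a single fixed learning rate (default 3e-3),
recorded in the training report. After each epoch the hard validation
DICE (mean of the two foreground classes over validation frames) is
evaluated and the best checkpoint is kept, ties resolved toward the
earlier epoch. All convolutions are BLAS-backed im2col matrix products
implemented in the package; the backward pass is verified against
finite-difference gradients in the test suite.

Splitting is subject-disjoint (`grouped_split()`): every phantom subject
contributes all of its frames to exactly one partition. For one-study-
per-subject data, subject-level disjointness is the strictest of the
image/study/patient levels and implies the others.

**Scale.** The model defaults to a 256 px input, the conventional size
for this kind of segmenter. The package's own training experiment — the
one the tests and the acceptance script run — uses a 64 px input, depth
2, 8 base channels, 200 frames from 50 subjects, and 12 epochs. That
scale trains in a few minutes on one CPU core and reaches validation
DICE ≈ 0.99 on the default phantoms (the acceptance floor is 0.85); it
is a desk-scale surrogate for, not a claim of equivalence to, a
production model.

`reference_segment()` is a second, deterministic segmenter for phantom
frames only: bone is thresholded at intensity ≥ 0.60, the head at
≤ 0.20, followed by minimum-area cleaning, largest-component selection
and hole filling. Its role is to decouple geometry and decision tests
from training stochasticity; it exploits the phantom's contrast design
and is not an ultrasound segmenter. An undetectable head yields an empty
class 2 rather than an error, so the adequacy gate can see the missing
landmark.

## Geometry

All measurement happens on label masks, after largest-connected-
component cleaning per class.

- **Baseline.** The per-row lateral edge (minimum column) of the class-1
  component is split into two runs by an exhaustive two-segment total-
  least-squares breakpoint search; the breakpoint estimates the bony rim
  row. The final line is a TLS fit through the per-row *midpoints* of the
  iliac stroke, which recovers the stroke's center line independently of
  stroke width (an edge-based fit would sit half a width lateral and
  bias coverage). The estimated half-width travels with the fit.
- **Roof.** Class-1 pixels farther from the fitted baseline than an
  adaptive separation (max of 4.2 px and 1.6 × half-width + 1, so the
  criterion scales with resolution) form the roof limb; a TLS line is
  fitted through all of them. The principal axis of a thick straight
  stroke is its center line, so thickness does not bias the angle.
- **Alpha.** The angle between the baseline direction canonicalized to
  point inferiorly and the roof direction canonicalized to point
  medially — invariant to the sign of either fitted direction, and able
  to represent α > 90°. Angles below 1° raise a degenerate-configuration
  error rather than returning a silent near-parallel value.
- **Head.** An algebraic (Kasa) least-squares circle through the boundary
  pixels of the class-2 component; on an exact rasterized disk of radius
  ≥ 20 px the center and radius are recovered to within a pixel.
- **Coverage.** `clip((r + s)/(2r), 0, 1)` with `s` the signed
  center-to-baseline distance, positive medially — the diameter-fraction
  (Morin d/D) operationalization of "femoral head coverage", which is
  analytically testable and matches the extreme-point pixel projection
  of the rasterized disk to within 0.01.

`measure()` never raises on incomplete masks: missing landmarks and
suspect fits set quality flags (`MISSING_CLASS`, `HIGH_LINE_RESIDUAL`,
`HIGH_CIRCLE_RESIDUAL`, `SMALL_HEAD`, `DEGENERATE_ANGLE`) and leave the
affected index absent. Residual thresholds default to 2.5 px for lines —
a stroke of width w fits its center line with RMS ≈ w/√12, so this
tolerates the rendered 6 px strokes with headroom — and 2.0 px for the
circle.

Numerical behavior worth knowing: on noise-free phantoms measured
through the reference segmenter, mean |α error| ≈ 0.4° and mean
|coverage error| ≈ 0.003 over the α ∈ [40, 75]°, coverage ∈ [0.2, 0.8]
range; both are an order of magnitude inside the package's acceptance
bounds (2°, 0.05). Alpha and coverage are stable to ±10° mask rotation
(within 1°/0.02) and to 2× upsampling (within 0.5°/0.01).

## Gating and decision

A frame is **adequate** when both landmark classes are present with at
least `min_class_area_px` (default 40) pixels, both line fits are within
the residual bound, the circle fit is within its bound, and the fitted
head radius is at least 8 px. Failures are enumerated reason codes, not
exceptions. `capture_loop()` emulates the on-probe experience: frames
are scanned in acquisition order and capture stops as soon as
`min_adequate_frames` adequate ones exist.

`decide_sweep()` gates every frame, and:

- fewer than `min_adequate_frames` (default 5) adequate frames →
  **INCONCLUSIVE** (repeat scan), with no aggregates — this encodes the
  design position that no diagnosis should be emitted from inadequate
  imaging;
- otherwise the **median** alpha and coverage over adequate frames are
  compared against the Graf cutoffs (α ≥ 60°, coverage ≥ 0.50, boundary
  equality healthy): both satisfied → **HEALTHY**, else **FOLLOW_UP**.

Open choices and how they were fixed: the aggregation statistic is the
median (robust to the occasional outlier frame that slips past the
gate); per-sweep aggregation rather than best-single-frame selection
(uses all evidence, and is order-free — permuting frames cannot change
the decision, which the tests assert); boundary equality counts as
healthy (a convention that had to be fixed; both cutoffs are
configuration values, not constants); `min_adequate_frames = 5` (small
enough for desk-scale sweeps, large enough that the median is a real
aggregate). With ≤ 2° measurement error, sweeps constructed at
α ≥ 63° and coverage ≥ 0.55 always classify healthy and sweeps at
α ≤ 55° always follow-up; the 5°/0.05 margins absorb the measurement
noise, and the separation is verified end to end in the tests.

Two hips combine to one infant-level outcome by clinical conservatism:
any follow-up hip → FOLLOW_UP, else any inconclusive hip → SUBOPTIMAL
(repeat), else NORMAL.

## Program statistics

The ledger holds one row per infant (latest status). Category
percentages are always `100 × count / total infants`, rounded half away
from zero to a per-field precision, so a reported percentage can always
be recomputed exactly from its integer count — the summary never stores
a percentage its count disagrees with. The denominator is unique
infants, not scans. The packaged 306-infant ledger
(`pilot_ledger()`, CSV copy in `inst/extdata/`) is synthetic: its
marginal counts (18/244/12/32 initial outcomes, 26/6 follow-up
resolutions, 6/6 referrals treated, 156 female) are the meaningful
content; row order, dates and site assignments are deterministic
plumbing. One arithmetic quirk is preserved deliberately: the
26-of-306 follow-up-resolved-normal category computes to 8.5% under
this package's rounding; an 8.2% figure sometimes quoted for that count
is not reproducible from a 306 denominator, so this package reports the
recomputable value.

`rolling_fu_rate()` produces the learning-curve series: records ordered
by scan date (ties by subject id), and for each position from the
window size onward the trailing-window proportion of initial outcomes
that triggered internal follow-up. Infants who could not be scanned stay
in the denominator — the rate is "per scan attempted", matching how a
program would audit its own workload. The series is
translation-invariant in time and is checked elementwise against a
closed-form sliding count.

## What the synthetic evaluation shows — and what it cannot

Passing tests establish that every stage is internally correct: the
geometry recovers construction truth, the loss matches its brute-force
definition, the gate rejects exactly the frames built to be inadequate,
the decision rule separates hips whose true indices sit 3°/0.05 beyond
the cutoffs, and training on phantoms converges and generalizes across
phantom subjects. None of this measures clinical performance: the
phantoms do not contain the anatomy, artifacts or operator variability
that make real hip ultrasound hard, the reference segmenter would not
work outside the phantom contrast design, and the desk-scale network has
not seen a clinical image. The cohort statistics module, by contrast,
computes exact arithmetic whatever the data source, and is directly
usable on real ledgers.

## Reproducibility

Every stochastic step — phantom speckle, dataset draws, weight
initialization, the grouped split, epoch shuffling — consumes an
explicit integer seed, and identical seeds reproduce results bit-for-bit
on one device (single-threaded BLAS). `scripts/acceptance.R` re-derives
the headline quantities from a single `--seed`; the problem sizes it
uses (50 recovery phantoms, 24 decision sweeps, a 200-frame training
corpus at 64 px) are the package's chosen desk scale, stated above.
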