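---
title: "Calcium microdomain analysis with microdart: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calcium microdomain analysis with microdart}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microdart)
```

## Scientific setting

Stimulating an immune cell with an antibody-coated bead triggers, within a
few seconds, small transient regions of elevated free Ca²⁺ near the plasma
membrane. In ratiometric imaging two indicators with opposite Ca²⁺
response are recorded simultaneously; their per-pixel ratio cancels
dye-loading and illumination artifacts, so a microdomain appears as a
localized, short-lived peak in the ratio image. The quantity of interest
at the population level is *where* and *when* these events occur relative
to the bead contact — which requires putting every cell of a group into a
common spatial (contact-aligned, shape-normalized) and temporal
(contact-shifted) frame before aggregating.

This vignette records the models, parameter choices and numerical
decisions behind each stage. Nothing here states an empirical result that
the test suite or `scripts/acceptance.R` does not itself compute.

## Postprocessing

**Registration.** The two indicator channels share one camera chip behind
an emission splitter and are typically misaligned by a fraction of a
pixel up to a few pixels. `register_channels()` maximizes normalized
cross-correlation (NCC): a regularized phase-correlation peak provides the
integer-pixel start (plain spectral whitening fails on smooth, band-limited
cell images, so the cross-power spectrum is damped by 1% of its maximum
magnitude), Nelder–Mead refines the translation, and an optional affine
stage refines a full 2×2 matrix *parameterized about the image center* —
without the centering, matrix and offset are so strongly coupled that the
simplex stalls. By default only the first frame pair is registered and the
transform reused (`register_mode: first_frame`); per-frame registration is
available. Resampling is bilinear by default; nearest-neighbor is exposed
for workflows where resampled intensities must remain original values.

**Background.** `max(I − bg, 0)` with `bg` a constant, a fixed-ROI mean,
or the per-frame darkest percentile (default: 1st percentile). Clipping at
zero can "vanish" dim cells if the background is overestimated — a known
failure mode; the pipeline logs and skips such cells rather than aborting.

**Ratio.** `ch1/ch2` elementwise; denominators ≤ 1e-12 give ratio 0
rather than NaN. A zero can never be detected as a microdomain because the
detection threshold is a multiple (> 1) of the mean cell intensity, so
this choice keeps the connected-component stage free of special cases.

**Bleaching.** Three corrections operate on the masked (in-cell) mean
`m(t)` with a target value `M` (default: the first frame's mean):

* additive: `I(t) + (M − m(t))` — used for the down-going indicator
  channel in the ratiometric workflow; it may push background pixels
  slightly negative, which the pipeline zeroes before ratio computation;
* multiplicative: `I(t) · M / m(t)`;
* biexponential: fit `f(t) = a + b₁e^(−t/τ₁) + b₂e^(−t/τ₂)` to `m(t)` by
  Levenberg–Marquardt (`minpack.lm`), subtract `f(t) − f(0)`.

Both frame-wise corrections make the masked mean exactly constant (float
precision); this is asserted on random stacks in the test suite. The
biexponential fit enforces τ > 0, resolves the exchange degeneracy of the
two terms by reporting τ₁ ≤ τ₂, multi-starts from three amplitude splits,
and treats a constant trace as the degenerate `b₁ = b₂ = 0` fit rather
than an error. Fits are only attempted on traces of ≥ 6 points.

## Deconvolution

Per-frame Richardson–Lucy with `u₀ = d` (the observed frame), default 10
iterations. Design points: boundaries are handled by reflective padding —
total intensity is then conserved to well under 1% for compact objects,
which matters because the later detection threshold is relative to the
mean; positions where the blurred estimate is ≤ 1e-12 receive ratio 1 (no
update) so the iteration cannot divide by zero; negativity from FFT
round-off is clamped. The convolution is an FFT circular convolution on
the reflect-padded frame, cross-checked in the tests against an
independent direct-loop implementation. Temporal-coupling deconvolution
methods are deliberately out of scope; the per-frame method is exposed
behind a single config key (`deconvolve`), and any alternative can be
applied upstream of the pipeline.

## Detection, tracking, ROI extraction

The default segmentation backend is classical — Gaussian smoothing, Otsu
threshold, hole filling, watershed on the distance transform, minimum-area
filter — because it is fully reproducible without trained weights. Any
stronger segmenter (e.g. a deep-learning model) can be passed as a
function returning a label matrix; the rest of the pipeline only consumes
masks, centroids and boundary polylines.

Frame-to-frame linking is an optimal assignment (Hungarian, via
`clue::solve_LSAP`) on centroid distance, gated at `max_disp_px`, with
dummy-augmented cost matrices so unequal object counts and gated-out pairs
are handled exactly; tests verify optimality against exhaustive
permutation matching. Gaps up to `max_gap` frames (default 2) are bridged.
`min_frames` defaults to the number of frames spanning 1 s before to 15 s
after the earliest bead contact, so only cells observable over the whole
analysis window enter the statistics.

ROI extraction re-centers the cell with *integer* shifts only. This keeps
every retained intensity value identical to the source — important because
the microdomain threshold is relative and interpolation would smear
extremes.

## Shape normalization

For each frame the boundary polyline is converted to polar samples
`(r_o, θ)` about the mask centroid (angles counterclockwise from +x, "up"
= decreasing row). The cell is mapped onto a circle of radius
`c · r_av`, `r_av = Σ r_o,i/N`, by radial scaling at fixed θ. The output
is built through the inverse map with nearest-neighbor sampling — both the
angular lookup of `r_o(θ)` (nearest sampled boundary angle) and the image
resampling are nearest-neighbor.

Design decisions:

* **One template per trace.** The template radius is `c` × the
  trace-median `r_av`, not the per-frame value, so a deforming cell does
  not breathe against its own dartboard; per-frame templates would alias
  deformation into apparent radial event motion.
* **`c = 1`** by default; the scale factor only changes the template size,
  not the statistics, since dartboard positions are relative.
* **Non-star-convex outlines.** When a ray from the centroid crosses the
  boundary more than once the outermost crossing is used (duplicate-angle
  samples collapse to the largest radius). Strongly concave cells violate
  the model's assumption and are the method's known failure mode; the
  generator can produce only star-convex shapes by construction, which is
  exactly the validity domain.
* The mapping preserves angles and is monotone in r, but it is **not**
  area-preserving; the dartboard's per-area normalization absorbs the
  radial distortion.

A practical nearest-neighbor caveat verified in the tests: where the map
expands radially (r_o(θ) > template radius), structures narrower than the
expansion factor can be aliased; the acceptance fixture therefore uses a
spot wider than the local magnification.

## Microdomain detection

A microdomain in frame t is a connected set of cell pixels with
`I(p)/mean(I over cell mask) > threshold`, of size within
`[min_size, max_size]`. Defaults: threshold 2.0, min 4 px, max 200 px,
8-connectivity — deliberately conservative defaults surfaced in the
config, to be calibrated per imaging setup (ideally against a noise
analysis of that setup). The mean is taken over the *full* cell mask,
including candidate pixels. Relative thresholding makes detection exactly
invariant to global intensity scaling, which the suite asserts for scale
factors over ten orders of magnitude. Component labeling is an in-package
BFS supporting both connectivities (tested for exact agreement with an
independent graph-component oracle); detection runs on shape-normalized
frames by default, with a switch to run before normalization.

A cell is *activated* if it shows ≥ 1 domain in ≥ `min_active_frames`
(default 1) frames from contact onward, within the analysis window
(default 1 s before to 15 s after contact). Group aggregation reports the
activated fraction and per-timepoint mean ± SEM; a single-cell group
reports SEM 0 with an explicit `sem_defined = FALSE` flag.

## Dartboard projection

Clock convention: bead-contact positions are hours on a clock face
overlaid on the image, 12 = up, increasing clockwise;
`angle = π/2 − clock·π/6`. After alignment every cell's contact direction
points at the reference angle (default 0, "3 o'clock"); segment 1 is
*centered* on it, so "near contact" is one segment rather than a segment
boundary. Ring radii `r_k = R√(b² + k(1−b²)/n)` make all annuli equal in
area (exact; asserted to machine precision); defaults are 12 segments,
5 rings, bullseye fraction 0.2, time bins 0–5/5–10/10–15 s. Events are
assigned by domain centroid — one domain, one count. Densities are pooled
counts divided by segment area × bin duration × number of cells; pooling
(rather than per-cell normalization before averaging) is the package's
contract and is stated in the exported long-format table. A centered
moving average over uniform fine bins supports finer temporal profiles;
edge bins use the partial window.

## Synthetic data generator

The generator emulates the structure of a bead-stimulation experiment:
star-convex cells (radial Fourier perturbation of a circle, slowly
rotating phases for deformation), a rising indicator channel and a falling
one, Gaussian event spots placed preferentially near the contact
(within ±1 clock hour and r/R ≥ 0.6), biexponential bleaching of the
falling channel, Gaussian read noise with optional Poisson shot noise, and
an optional known sub-pixel channel misalignment. All randomness is under
one seed; output is bit-reproducible.

Defaults (the simulated "study conditions"): cell radius 18 ± 2 px
(≈ 6–7 µm at typical magnification), channel baselines 100/120 with
background 8, event amplitude 3× the cell mean with σ = 1.5 px lasting
2 frames, near-contact rate 1.0 events/s vs background 0.1 events/s (10×
enrichment), read noise σ = 5 (5% of the cell mean, putting the default
detection threshold at roughly 5σ of background relative intensity), and
bleaching fractions a = 0.35, b₁ = 0.25, b₂ = 0.40. The decay constants
τ₁ = 3 s, τ₂ = 12 s are chosen so that both components decay appreciably
*within* the ~17.5 s record — a slow component much longer than the
acquisition would not be identifiable from the data and would make any
recovery check a test of extrapolation rather than of the fitter.

What the generator does **not** emulate: indicator photophysics (Kd, Hill
binding), PSF-accurate optics (blur is Gaussian), cell contact
deformation at the bead, or drift-induced rotation. Passing tests on this
generator therefore demonstrate the pipeline's internal consistency and
its recovery of known spatial/temporal/photometric structure — not
biological fidelity of any particular dataset.

## The recovery experiment

`recovery_experiment()` is the package's canonical self-check and the
computation behind `scripts/acceptance.R`: 20 cells in a 190×235 px field,
36 frames at 0.5 s (contact at frame 4, so the −1…+15 s window fits),
a known (0.6, −0.4) px inter-channel shift, and the generator defaults
above. It reports: the registration error against the known shift; the
bleaching-τ errors from refitting the generated falling-channel trace
(the per-frame cell *median* is fit rather than the mean, because Ca²⁺
events transiently depress a few dozen pixels and the median is robust to
such localized excursions); detection precision/recall against the
ground-truth event list (3.5 px, event-duration matching, on
un-normalized ROIs so positions compare directly); the activated-cell
fraction; and the dartboard density contrast between the contact-centered
segment and the opposite side. The contrast ratio is reported against the
pooled opposite 90° *arc* rather than the single opposite segment: at the
simulated background rate the single opposite segment is empty in a
sizeable fraction of runs, which would make a single-segment ratio
undefined rather than informative.

These problem sizes run the whole experiment in well under a minute on a
single CPU; they are the package's chosen benchmark conditions, not a
constraint of the method.

## Known limitations

* Shape normalization requires approximately star-convex outlines; frayed
  or highly concave cells are flagged and skipped, not repaired.
* Cells partially outside the field of view fail ROI extraction by design.
* Linking handles translation only — no mitosis, merging, or rotation
  compensation.
* The biexponential bleach model assumes monotone decay; strongly
  non-monotone traces fall back to the frame-wise corrections.
* TIFF is the only native format; convert upstream if needed. Float
  stacks are stored as scaled float32 with a sidecar scale file
  (bit-exact round trips are guaranteed for integer data only).
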