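---
title: "Catheter reconstruction in dual-contrast MR: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Catheter reconstruction in dual-contrast MR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cathrecon)
```

## The reconstruction problem

During template-based interstitial gynecological brachytherapy, 15–20
hollow plastic catheters are implanted trans-perineally and a source is
stepped through them at discrete dwell positions. Treatment planning
requires each catheter's trajectory on the planning MR volume. With MR
line markers, catheter cross-sections are *hyperintense* on T1-weighted
and *hypointense* (signal voids) on T2-weighted images; air cavities
mimic the T2W appearance, which is what makes purely intensity-based
detection unreliable and motivates a learned detector.

`cathrecon` separates the problem the way a planner works:

1. a per-slice detector proposes candidate cross-sections
   (segmentation stage), and
2. a deterministic tracker strings candidates into one ordered path per
   catheter, from a manually seeded template plane down to a stopping
   slice fixed by the catheter's physical geometry (post-processing
   stage).

The split matters: the learned stage only needs decent per-slice recall,
because the tracker enforces the strong prior that catheters are
near-axial curvilinear structures with bounded slice-to-slice drift and
known insertion depth, and it can impute isolated detection dropouts.

## Segmentation stage

### Architecture

The network is a standard 2D U-net: five encoder levels (two 3×3
convolutions + ReLU per level, 2×2 max pooling between levels), four
decoder levels (2×2 transposed convolution + ReLU, concatenation of the
matching encoder feature map, then two 3×3 convolutions + ReLU), and a
final 1×1 convolution with sigmoid. With the canonical widths
64→128→256→512→1024 and one input/output channel the trainable-parameter
count is 31,030,593 (`unet_parameter_count()`), and a 128×128 input
reaches an 8×8 bottleneck. Channel widths are configurable; desk-scale
work in this package uses 8→16→32→64→128 (~486k parameters), which is
deep enough to separate bright/dark blobs from texture on phantom data.
No batch normalization or dropout is used. One model is trained per MR
contrast; the contrasts are never mixed inside a network.

All kernels (convolution, pooling, transposed convolution, forward and
backward) are compiled single-precision RcppArmadillo code; the test
suite checks the backward pass against finite differences and the
parameter count against an independently coded layer sum.

### Loss, initialization, optimization

Training minimizes the smoothed Dice loss
`1 − (2 Σ p·t + ε) / (Σ p + Σ t + ε)` with ε = 1 in both numerator and
denominator. The smoothing term exists to keep the loss defined (and
zero) when a patch contains no catheter at all; adding ε only to the
numerator would leave the empty/empty case undefined, so the standard
both-places form is used.

Weights are He-normal; the final-layer bias is initialized to −3
(`init_bias`), i.e. an initial foreground prior of about 5%. Catheter
cross-sections occupy well under 1% of a 64×64 patch, and a network
that starts at a 50% prior spends most of a short schedule just
suppressing background mass in the Dice denominator; starting near the
true prior removes that transient. Optimization is Adam with per-batch
global gradient-norm clipping at 5 — Dice gradients spike when a
prediction collapses toward empty, and without clipping we observed
entire runs destabilized by single batches at learning rates that are
otherwise fine.

Two learning-rate regimes are relevant. The full-scale configuration
(canonical widths, 100 epochs, batch 8, learning rate 1e−5) is the
package default. The scaled configuration used by the tests and the
acceptance script (widths 8–128, 10 epochs, 1000 balanced patches per
contrast) uses 3e−4: small networks on short schedules need a larger
step to converge, and at 1e−3 we observed occasional mid-run divergence,
so 3e−4 is the shipped value.

### Patches and augmentation

Training patches are 64×64, sampled half centered on labeled catheter
cross-sections (with ±6 voxel jitter) and half at background positions;
class balance prevents the trivial all-background solution. Half the
patches are randomly perturbed by translation (±8 px), isotropic scaling
(0.9–1.1) and in-plane rotation (±15°), with the label transformed
identically and re-binarized at 0.5. Inference tiles each slice with
overlapping windows (stride = half the patch size) and averages
overlapping predictions; windows at the borders are shifted inward
rather than zero-padded. The binarization threshold is strictly
`p > 0.5`: a pixel at exactly 0.5 is background.

## Post-processing stage

Per slice and contrast, candidates are centroids of 8-connected
components of the binary mask (a minimum component size filter exists
but defaults to 1, i.e. off). Each candidate is refined to the intensity
extremum of its own contrast — argmax for T1W, argmin for T2W — inside a
rectangle of half-size 5 voxels (~2.7 mm at 0.53 mm pixels) around the
candidate; ties break by proximity to the approximate position, then
row-major order. The rectangle size is a design choice: it must cover
the catheter cross-section plus localization slack but stay below the
typical 5–10 mm inter-catheter spacing of a perineal template.

Refined T1W and T2W candidates within 2 voxels of each other merge to
their coordinate mean (dual-contrast detections); unmatched candidates
survive as single-contrast detections, so either contrast alone can
carry a catheter through slices where the other fails.

Tracked catheters then link to candidates by greedy one-to-one
nearest-neighbor assignment within an 8-pixel neighborhood. One-to-one
matters: plain per-catheter nearest-candidate would let two adjacent
catheters collapse onto one detection. A catheter with no candidate in
reach is a *jumping catheter*; its position is imputed by adding the
mean **absolute** per-axis displacement of the detected catheters to its
previous position. The absolute-value form is implemented verbatim; note
that it biases corrections toward positive row/column for implants whose
catheters drift in opposing directions, which is why a signed-mean
variant exists behind `signed_jump_correction = TRUE` (default off, for
sensitivity analyses only). When *nothing* is detected on a transition
the correction is undefined (its denominator is the number of detected
catheters); positions then carry over unchanged, which keeps every path
total.

Each path runs from the template plane `m` to
`m + floor((total − free − template) / slice thickness)`: catheters are
assumed near-axial, so insertion depth in mm maps to a slice count. An
arc-length-based stop (accumulate 3D path length instead) would differ
only for strongly curved catheters and is not implemented; at the
curvatures the phantom generates (≤ 1 voxel/slice) the difference is
below one slice.

Coordinates are 1-based `(row, col, slice)` voxel indices, with physical
coordinates `(index − 1) × spacing` mm; exported JSON and CSV record
both.

## Evaluation

Paths are resampled by piecewise-linear arc length into dwell positions
at 1 mm intervals, always including the terminal point (the tip is
clinically salient even when the last interval is short). Deviation is
measured per dwell as the distance to the **nearest point of the
reference polyline**, not to the same-index dwell: index pairing would
conflate longitudinal offset along the catheter (clinically benign,
correctable by indexer offset) with lateral error (the quantity that
moves dose). A paired-index mode exists behind a flag for sensitivity
checks. Summary statistics pool all dwells (with a per-catheter
breakdown alongside), and the report adds the Dice overlap of the two
path sets rasterized with the same disk radius used for training labels,
and the symmetric point-set Hausdorff distance on the dwells.

## The phantom generator

`generate_phantom()` emulates the acquisition geometry and contrast
behaviour the method depends on, not MR physics:

* voxels 0.5327 × 0.5327 × 1 mm (the clinical protocol's grid);
* catheter tracks as smooth random walks — per-slice Gaussian steps,
  low-pass filtered, rescaled so no step exceeds the configured
  curvature (default 0.8 voxels/slice) — seeded on a jittered template
  grid with ≥ 8 voxel separation;
* cross-sections rendered with a Gaussian radial profile (σ =
  radius/1.6, nominal radius 2 voxels ≈ a 6F catheter at this pixel
  size), added to background: +60 in T1W, −60 in T2W. The smooth
  profile reflects partial-volume falloff at catheter edges and gives
  the intensity-extremum refinement a real peak to find;
* background: mean 100 with smoothed-noise texture (sd 12), plus
  additive white noise (sd 8) — contrast-to-noise around 7, i.e.
  conspicuous but not noise-free markers;
* dark ellipsoidal cavities (default 3) subtracted from *both*
  contrasts, placed away from every track: the classic T2W confounder;
* insertion depths drawn per catheter at 70–95% of the stack depth, so
  stopping slices genuinely differ between catheters; total length is
  fixed at 294 mm (standard 6F catheters) and free length is derived.

Everything is a deterministic function of `rng_seed`. What the phantom
does **not** emulate: bias fields, k-space/motion artifacts, anatomy,
inter-patient contrast variability, or markerless catheters. Passing
phantom tests therefore demonstrates that the algorithmic chain is
correct and recovers known geometry under realistic contrast polarity,
noise and confounders — not that the shipped small networks would
segment clinical MRI; the full-scale training regime exists for that and
requires real labeled data.

## Numerical choices and degenerate inputs

* Refinement ties (uniform rectangles) return the rounded approximate
  position itself; ties elsewhere resolve by row-major order, so runs
  are bit-reproducible.
* Stopping-slice arithmetic floors with a 1e−9 guard so exact-multiple
  insertion depths don't lose a slice to floating point.
* `normalize_volume()` refuses constant volumes; `dice_loss()` and the
  mask/volume entry points validate shapes and ranges and fail loudly.
* Zero-insertion geometries yield a single-point path (the seed); its
  dwell set is that one point.
* Empty masks on a slice are legal input everywhere: candidates are
  empty, every active catheter jumps, positions carry over.

## Problem sizes used by the shipped experiments

The test suite and `scripts/acceptance.R` use 96×96×40 phantoms with 10
catheters; the scaled network (widths 8–128) trains for 10 epochs on
1000 balanced 64×64 patches per contrast with batch size 8. On these
sizes the oracle-mask experiment recovers dwell positions to ~0.2 mm
mean deviation and the end-to-end experiment reaches held-out
segmentation Dice around 0.7 with all catheters tracked — numbers the
acceptance script recomputes on every run rather than this vignette
asserting them as fixed facts.

## Known limitations

* The tracker assumes one seed per true catheter on the template plane;
  it will not discover unseeded catheters (by design — the clinical
  workflow seeds them manually) and never merges or splits paths.
* The absolute-value jump correction is directionally biased (see
  above); with many simultaneous dropouts on implants drifting in mixed
  directions, imputed positions drift positive.
* Near-axial geometry is assumed by the mm→slice stopping rule; steeply
  angled catheters would stop early.
* The two volumes are assumed co-registered (single-exam T1W/T2W); no
  registration is performed.
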