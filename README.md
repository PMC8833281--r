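# cathrecon

Semiautomatic reconstruction of interstitial brachytherapy catheters in
paired T1-weighted/T2-weighted MR volumes.

## The problem

High-dose-rate (HDR) gynecological interstitial brachytherapy delivers
radiation by stepping a source through 15–20 plastic catheters implanted
through a perineal template. Planning the treatment requires digitizing
every catheter's 3D trajectory on the planning images so that source
dwell positions can be placed along it. On MRI — the preferred planning
modality for its soft-tissue contrast — plastic catheters are hard to
see: with marker wires they appear as *bright* spots on T1-weighted
images and as *signal voids* (dark spots) on T2-weighted images, and are
easily confused with air cavities. Manual reconstruction takes an expert
the better part of an hour per implant and is a recognized source of
error; reconstruction deviations above 2 mm can have dosimetric
consequences.

`cathrecon` implements a two-stage semiautomatic pipeline for this task,
for medical-physics researchers working on MR-only brachytherapy
workflows:

1. **Segmentation.** One 2D U-net per MR contrast (trained on 64×64
   axial patches with a smoothed Dice loss, `1 − (2Σpt + ε)/(Σp + Σt + ε)`)
   produces a per-pixel catheter probability map for every slice;
   pixels with probability > 0.5 are catheter candidates.
2. **Deterministic post-processing.** On each slice, 8-connected
   components of the binary masks yield candidate positions; each is
   refined to the local intensity extremum (argmax in T1W, argmin in
   T2W) inside a small rectangle; the two contrasts are fused; tracked
   catheters link to their nearest candidate within an 8-pixel
   neighborhood (greedy one-to-one). A catheter with no candidate in
   reach — a *jumping catheter* — is imputed by adding the mean absolute
   per-axis displacement of the detected catheters,
   `Δx = mean |x_{n+1} − x_n|`, `Δy = mean |y_{n+1} − y_n|`, to its previous
   position. Reconstruction starts from manually seeded positions on
   the template plane and stops per catheter after
   `total length − (free length + template thickness)` mm of depth.

Reconstructions are evaluated by resampling each path into dwell
positions at 1 mm arc-length spacing and measuring per-dwell deviation
from the reference path (nearest point on the polyline), plus the Dice
overlap of rasterized paths and the symmetric Hausdorff distance.

Because no clinical MR data ship with the package, it includes a
synthetic dual-contrast phantom generator (`generate_phantom()`) that
renders smoothly curving catheter tracks — bright in T1W, dark in T2W,
with tissue-like background texture, noise, and dark cavity
confounders — together with exact ground-truth trajectories.

The U-net itself (forward and backward passes, Adam, Dice loss) is
implemented natively in the package with compiled RcppArmadillo kernels,
so the whole pipeline runs on a plain R installation with no deep
learning framework.

## Worked example

```r
library(cathrecon)

# a 96 x 96 x 40 phantom (0.5327 x 0.5327 x 1 mm voxels), 10 catheters
ph <- generate_phantom(phantom_config(rng_seed = 1))

# reconstruction driven by ground-truth-derived masks
mask <- rasterize_truth_mask(ph$paths, ph$config$shape, radius = 2)
rec  <- reconstruct_catheters(normalize_volume(ph$t1w),
                              normalize_volume(ph$t2w),
                              mask, mask, ph$geometry)
report <- evaluate_reconstruction(rec, ph$paths, ph$config$spacing_mm,
                                  shape = ph$config$shape)
print(report)
#> <eval_report> 338 dwells: 0.18 +/- 0.11 mm; 100.00% < 2 mm, 0.00% > 3 mm
#>   path DSC 0.806, mean Hausdorff 0.57 mm
```

The 338 dwells are the 1 mm-spaced source positions along all ten
reconstructed paths; the mean 3D deviation from the known truth is
0.18 mm — about a third of an in-plane voxel — with every dwell within
the 2 mm clinical tolerance. With masks predicted by the trained
networks instead of oracle masks (see `run_pipeline()` with
`mask_source = "unet"`), deviations stay near one voxel and held-out
segmentation Dice is around 0.7 on phantom data.

The full pipeline, including training both networks, fits in one
config-driven call:

```r
run_pipeline(list(
  phantom = list(rng_seed = 1),
  mask_source = "unet",
  unet = list(widths = c(8, 16, 32, 64, 128),
              learning_rate = 3e-4, epochs = 10),
  out_dir = "out"
))
```

A command-line front end with `simulate`, `train`, `predict`,
`reconstruct`, `evaluate` and `run` subcommands is installed at
`inst/cli/cathrecon.R`.

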