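---
title: "Spatial TIL scoring and immune subtyping: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial TIL scoring and immune subtyping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(TILscore)
```

## The problem and the model

Tumor-infiltrating lymphocytes (TILs) concentrate in the stroma of lung
adenocarcinoma, and both their abundance and their spatial arrangement track
the activation state of the tumor immune microenvironment. Transcriptomic
immune subtyping ("hot" vs "cold", here `Immunity_H` vs `Immunity_L`) is the
reference standard but is costly and destroys spatial information. TILscore
implements an interpretable rule that predicts the immune subtype directly
from slide annotations — tissue contours, tumor-parenchyma regions, and TIL
detections, such as a segmentation/detection pipeline or a pathologist's
QuPath session exports.

The rule has four steps, each inspectable on its own:

1. **Patch grid.** The bounding box of the tissue contour is tiled with
   non-overlapping 100 μm × 100 μm patches (the sliding window's step equals
   its size; the score's denominator counts patches, which presumes a
   partition). Patches are half-open squares `[x0, x0+s) × [y0, y0+s)`, so a
   detection center on a shared edge belongs to exactly one patch.
2. **Stromal counting.** A detection is counted iff its box center lies
   inside a tissue polygon and outside every tumor polygon. Each counted
   detection increments exactly one patch. `NumMax` is the maximum patch
   count on the slide; a patch is *valid* iff it holds at least one counted
   TIL.
3. **Normalization and attention.** Each patch gets a relative density
   `a = Num / NumMax` in [0, 1]. A patch is *high-attention* iff `a > 0.2`
   (strict). Pooled training densities are bimodal — a dense mass of sparse
   patches and a thin tail of focal aggregates — and 0.2 sits in the gap;
   `calibrate_attention_threshold()` re-derives a cutoff from data by
   Ward-linkage hierarchical clustering at k = 2, placing the threshold at
   the midpoint of the inter-cluster gap and falling back to 0.2 with a
   warning when the gap is below 0.02 (no bimodal structure to cut).
4. **Score and call.** `Score = N_high / N_valid`; the slide is called
   `Immunity_H` iff `Score > 0.05` (strict). `calibrate_score_threshold()`
   re-derives this cutoff by sweeping midpoints between consecutive sorted
   unique training scores, maximizing accuracy with Youden's J and then the
   smaller threshold as tie-breaks.

Both inequalities are strict throughout; a patch exactly at `a = 0.2` is
low-attention, a slide exactly at `Score = 0.05` is low-immunity.

### Degenerate slides

A slide with no counted stromal TIL has `NumMax = 0`, which makes
`a = Num/NumMax` undefined and `N_valid = 0`. The package defines this case
rather than erroring: all densities are set to 0, the score to 0, the label
to `Immunity_L`, and a loud warning is raised with the grid's `degenerate`
flag set. Real cohorts do not contain such slides, but simulated or
truncated inputs can.

## Coordinates and geometry

Annotation coordinates are level-0 pixels with a separate microns-per-pixel
scale (`mpp`), the convention of slide viewers; all micron-space computation
converts at the point of use (`μm = px × mpp`). Point-in-polygon uses the
even-odd rule with holes subtracting by parity; points exactly on a boundary
count as inside. These choices only affect a measure-zero set but make every
count fully reproducible. Self-intersecting polygon rings are repaired only
by dropping duplicate consecutive vertices; a ring that remains
self-intersecting (a bow-tie) is rejected with an error rather than
re-noded, because guessing the intended region from a corrupt annotation is
worse than failing.

## The synthetic cohort generator

The generator exists so every downstream stage can be tested end to end
without slide images. `simulate_slide()` draws:

* a tissue contour (rounded rectangle inset 8% from the slide bounds by
  default, 3 × 3 mm slide, mpp 0.5),
* tumor-parenchyma discs rejection-placed fully inside the tissue until they
  cover the target fraction (default 0.2) of tissue area,
* stromal TILs as a homogeneous Poisson background superposed with a
  Thomas-type cluster process: Poisson parents, Poisson cluster sizes,
  isotropic Gaussian offspring dispersion. Points are simulated on the slide
  frame and rejected outside the stroma, so under pure-Poisson settings the
  expected count is exactly `intensity × stroma area` — the property the
  test suite verifies by Monte-Carlo over 500 seeds.

Detections are emitted as 8 μm square boxes (the scale of a lymphocyte
nucleus) centered on the simulated points, since the scoring rules consume
box centers. All randomness flows from one explicit seed; cohorts derive a
per-slide seed from the base seed and the slide index, and no function
touches the caller's global RNG stream.

### Why the low-immunity preset is not strictly homogeneous

Max-normalization has a failure mode worth documenting. For a *purely*
homogeneous Poisson field with per-patch mean `m`, `NumMax` is the maximum
of ~10³ Poisson variates — around `m + 3√m` — so ordinary TIL-bearing
patches normalize to `a ≈ m / NumMax`, which exceeds 0.2 for every realistic
`m`. A homogeneous slide therefore scores *high*, regardless of how sparse
it is. Real low-immunity slides score 0.005–0.05, which implies they contain
at least occasional focal aggregates that pin `NumMax` well above the
background. The low preset encodes exactly that: background 80 cells/mm²
plus rare tight foci (0.8 parents/mm², mean 60 offspring, σ = 15 μm) whose
dense central patch anchors the normalization. The high preset differs by
abundant broad foci (4 parents/mm², mean 80 offspring, σ = 40 μm). With
these study conditions a 20 + 20 cohort is recovered at 97.5–100% by the
default rule; the residual failures are low slides whose Poisson focus
count realized zero, which is the degenerate homogeneous case above.

What the generator does **not** emulate: H&E color realism, staining
variation, nucleus morphology, detector false positives/negatives, tissue
folds, or the within-slide heterogeneity of real tumors. Passing the
recovery test therefore shows the *rule* behaves as designed on point
patterns with the assumed structure — not that any detector achieves this
accuracy on real slides.

### IHC count simulation

`simulate_ihc_cohort()` draws 10 field counts per case and marker from a
truncated-rounded normal (or a moment-matched negative binomial) with
group-separated means. The default means/SDs are the reported magnitudes
for CD3, CD8, CD20 and CD68 in high- vs low-immunity groups; CD20 was
reported as median (IQR), converted here as mean ≈ median and
SD ≈ IQR/1.349 under a normal approximation.

## The classical tissue-mask stage

`segment_tissue()` implements the non-learned contour pipeline: downsample
to the scale of a 2.5× objective (4 μm/px given the source mpp, or a fixed
1/16 factor when the scale is unknown), Roberts gradient magnitude binarized
by Otsu, unioned with a Canny detector at thresholds (30, 120) on the 0-255
gradient scale, two closings with a 3 × 3 elliptical element, border
flood-fill of interior holes, connected components, a 0.1%-of-frame speckle
filter, and contour tracing scaled back to input coordinates. Roberts, Otsu
and Canny are listed by the operating point without a stated composition;
the union was chosen because it maximizes weak-boundary recall, and the
ambiguity is intrinsic to the source description. Denoising in
`preprocess_image()` runs the median filter *before* the Gaussian so
impulse noise is removed rather than smeared; missing pixels are filled by
bilinear interpolation (row- and column-wise linear interpolation from the
flanking valid pixels, averaged).

On the bundled synthetic fixtures (tinted discs with Gaussian texture on a
near-white background, rendered at 8 μm/px) the pipeline recovers the
ground-truth mask at Dice ≈ 0.98. This exercises the classical stage only;
it says nothing about learned tumor-parenchyma segmentation, which is out
of scope.

## Heatmaps

`interpolate_density_surface()` realizes "spatial linear interpolation" as
bilinear interpolation between patch-center nodes on a fine lattice with
`upsample_factor` cells per patch edge; node `(i, j)` sits exactly at fine
index `(i·up+1, j·up+1)`, so the surface passes through the input densities
and, by convexity, never leaves their range. Colormap endpoints are fixed at
`a = 0` (blue) and `a = 1` (red) so colors are comparable across slides.
Cells outside the tissue contour are masked transparent by default (the
alternative — interpolating across non-tissue gaps — is available via
`mask_outside_tissue = FALSE`). Rendering is a pure function of surface and
configuration; repeated calls produce byte-identical PNGs.

## Evaluation statistics

* **Confusion matrix** with high-immunity as the positive class;
  accuracy, sensitivity, specificity, PPV and NPV as the usual margins.
* **Wilson score intervals** (z = 1.959964 at 95%) for every proportion.
  The Wilson interval was chosen because it reproduces the published
  external-validation CIs for accuracy, sensitivity, specificity and NPV
  exactly at one-decimal rounding; the published PPV interval (76.5–98.1 for
  26/28) is not a Wilson interval (Wilson gives 77.4–98.0) and the original
  method for that one interval is unknown. The implementation standardizes
  on Wilson and documents the discrepancy rather than special-casing PPV.
* **ROC/AUC** by the Mann–Whitney rank formulation with ties counting one
  half, cross-checked in the tests against brute-force pair counting and an
  independent ROC package.
* **IHC composite score**: per marker, the 10 field counts are trimmed by
  removing exactly one maximum and one minimum occurrence, averaged,
  converted to cells/mm² with the 0.2595 mm² high-power field, Z-scored
  across the cohort (sample SD), and averaged over the four markers; cases
  above the cohort median (strictly) are IHC-high. A marker with zero
  cohort SD carries no information and contributes Z = 0 with a warning.

## Problem sizes and determinism

The test suite and the acceptance script use sizes chosen to exercise every
code path at comfortable desk scale: 3 × 3 mm slides (≈ 900 patches,
600–2500 detections), cohorts of 20 + 20 slides, 100 randomized
count-conservation instances of up to 500 detections, 500 Monte-Carlo
replicates for the Poisson-mean check, and 60-case IHC cohorts. Every
stochastic step takes an explicit seed; the published ten-case worked
example and the confusion-matrix statistics are fully deterministic.

## Known limitations

* The score presumes a detector (or simulator) supplying TIL positions; no
  detection is performed here, and detector errors propagate directly into
  patch counts.
* Max-normalization couples every patch's density to the single densest
  patch, which makes the score sensitive to one extreme focus and undefined
  on TIL-free slides (handled by the degenerate convention above).
* The attention and score thresholds are published operating points from a
  modest training cohort; the calibration utilities re-derive them from
  data, but their generalizability to other cohorts, scanners and staining
  protocols is an empirical question the synthetic cohorts cannot answer.
* The tissue-mask stage targets clean, high-contrast synthetic rasters;
  real WSI thumbnails with pen marks, folds or weak counterstain will need
  parameter adjustment.
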