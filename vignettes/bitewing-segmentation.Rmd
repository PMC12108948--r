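---
title: "Projection-profile segmentation of bitewing radiographs"
author: "bwseg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projection-profile segmentation of bitewing radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bwseg)
```

## The problem

A bitewing radiograph captures the crowns of upper and lower posterior
teeth in one frame, separated by the dark occlusal band. Downstream
caries classifiers want one small image per tooth (or per half-tooth,
since proximal caries sits on the mesial/distal surfaces), but bitewings
are acquired at varying tilt angles, so fixed horizontal and vertical
cuts mis-split the teeth. `bwseg` implements a rotation-aware,
projection-profile segmentation: it first recovers the tilt, then cuts.

## The method

**Rotation search.** In the binarized image, bright teeth are foreground
and the occlusal band is background. For a candidate rotation angle the
image is rotated, smoothed, Otsu-thresholded, eroded horizontally, and
the *horizontal projection* (foreground count per row) is taken over the
central third of rows (the outer thirds are masked because only the
middle can contain the occlusal band). The minimum of that masked
profile — the *trough* — measures how cleanly a horizontal line can pass
between the jaws: when the band is level, some row crosses almost no
foreground. The search minimizes the trough over angle in two stages:
a coarse sweep at 5-degree steps over ±15 degrees, then 1-degree steps
within ±4 degrees of the coarse winner. The two-stage grid evaluates far
fewer angles than a flat 1-degree sweep while returning the same argmin
whenever the fine window covers the coarse winner's neighborhood; ties
are broken toward the smaller absolute angle, then the smaller signed
angle (a convention of this package; ties are rare in practice).

**Jaw and tooth cuts.** The image is rotated by the winning angle and cut
horizontally at the trough row. Per jaw, the *vertical projection*
(foreground per column) shows interdental gaps as valleys: candidate
separators are interior local minima whose topographic prominence is at
least a fraction (default 0.10) of the profile maximum, thinned to a
minimum spacing (default 1/16 of the row width, i.e. assuming at most
8 teeth per row). If the tooth count is known, the n−1 most prominent
valleys are kept; otherwise the count is inferred from the qualifying
valleys. n teeth always yield exactly n−1 separators, the column spans
of the resulting crops tile the row image, and each crop is optionally
trimmed vertically to its foreground extent. Each whole tooth can be
split at its box midline into left and right halves (odd widths give
the extra column to the right half — arbitrary but fixed).

**Reporting frame.** All boxes are reported in the rotation-corrected
frame together with the applied angle; `boxToOriginalFrame()` maps a box
back through the inverse rotation when the original frame is needed.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `sigma` | 1.5 | px | Gaussian denoising before thresholding; 0 disables |
| `erodeH` | width/50, odd | px | horizontal erosion length before the row projection |
| `erodeV` | row height/20, odd | px | vertical erosion length before the column projection |
| `range`, `coarseStep`, `fineStep` | 15, 5, 1 | deg | the two-stage angle grid |
| `fineHalfwidth` | 4 | deg | fine window half-width around the coarse winner |
| `minProminenceFrac` | 0.10 | — | valley prominence threshold, fraction of profile max |
| `minSeparationFrac` | 1/16 | — | minimum valley spacing, fraction of row width |

The erosion lengths scale with the image so that thin bright bridges
across the occlusal and interdental gaps (restoration overhangs, braces
wires, noise specks) are suppressed without erasing the teeth. The fine
half-width of 4 degrees makes the fine stage cover every integer angle
between adjacent coarse grid points of the winner. Angles are evaluated
on integer degrees only; the trough landscape is flat at sub-degree
scale and the downstream cuts are pixel-quantized, so a continuous
optimizer would add cost without adding accuracy.

## The enhancement bank

Three classical operators, all mapping [0, 1] into [0, 1]:

* **IAM** (intensity value mapping): saturating linear rescale between
  the image's 1st and 99th percentile intensities, then a gamma curve
  (default gamma 1). Monotone; a constant image maps to zeros.
* **HISTEQ**: global histogram equalization by the normalized cumulative
  256-bin histogram. Monotone; a constant image maps to 1 (its single
  bin carries the whole mass). The explicit CDF convention is documented
  so degenerate inputs behave deterministically.
* **AHE**: contrast-limited adaptive equalization on a tile grid
  (default 8×8), per-tile histograms clipped at a *fraction* of the tile
  pixel count (default 0.01, excess redistributed uniformly), bilinear
  interpolation between tile-center mappings. With one tile and clip 1
  it reduces exactly to HISTEQ — that identity is what fixes the shared
  histogram convention. AHE is not a global point mapping and is
  therefore excluded from the monotonicity guarantees.

`applyChain()` composes operators strictly left to right; the preset
registry names the eight studied configurations (`original`, each single
operator, `histeq+ahe`, `ahe+iam`, `iam+histeq`, `iam+histeq+ahe`,
where "a+b" means apply `a`, then `b`).

## The synthetic phantom

Clinical bitewings are IRB-restricted, so the package ships a generator
whose output carries exact ground truth. The canonical frame contains
two rows of bright rounded-rectangle teeth (intensity 0.75 ± 0.05 per
tooth, clipped to [0.4, 0.92]) on a 0.10 background, 600×400 px, four
teeth per jaw, separated by a 30 px occlusal band and 8 px interdental
gaps. Each tooth's occlusal edge protrudes into the band by 20–45 % of
its height: real occlusal surfaces are uneven and interdigitate, and
this irregularity is what makes the rotation search well-posed — with
perfectly straight edges every angle within roughly ±3 degrees of truth
would leave an identical empty corridor and the trough criterion could
not distinguish them (no method could). With probability 0.25 a tooth
gets a bright (0.95) occlusal restoration cap, and with probability 0.25
a dark semicircular caries notch on a proximal surface, mirroring where
secondary caries arises clinically; both probabilities are conventional
choices, picked once to exercise the lesion structures without
dominating the geometry. Gaussian noise (sd 0.02) is added, the image
is clipped to [0, 1] and rotated by the generator angle. All randomness
flows from one integer seed through an isolated RNG scope; the global
RNG state is untouched.

What the phantom does **not** emulate: gum and bone texture, tooth
overlap/contact, braces hardware, cervical burnout, scatter and
beam-hardening, variable exposure fields. Passing the phantom suites
therefore demonstrates the geometric correctness and robustness of the
algorithm under its stated assumptions — not clinical performance.

## Evaluation statistics

Confusion-matrix accuracy/precision/recall (undefined denominators
yield `NA`, never a silent zero; percentages render at two decimals,
rounding half away from zero), half-open-box IoU, all-point interpolated
average precision with greedy one-to-one matching at IoU ≥ 0.5, mAP as
the arithmetic mean of per-class APs, and a paired t-test on IoU values:
`t = mean(d) / sqrt(sum((d - mean(d))^2) / (N (N - 1)))` with a
two-sided p from Student's t on N−1 degrees of freedom (the two-sided
choice is this package's; a one-sided variant halves p). Zero-variance
differences are rejected as degenerate rather than returned as an
infinite statistic.

## Numerical choices and degenerate inputs

* Rotation uses bilinear interpolation about the image center, canvas
  preserved, corners filled with background (0); exact at multiples of
  90 degrees. Positive angles are counterclockwise; the binarization is
  recomputed after every rotation rather than rotating a binary mask,
  which would introduce nearest-neighbor stair-casing into the counts.
* Smoothing convolves a normalized discrete Gaussian truncated at
  3 sigma with edge-replicated borders, run as two separable 1-D passes.
* Erosion treats out-of-image pixels as background (the mask is
  zero-padded before the morphological kernel is applied), so border
  foreground erodes away — the projection counts then never credit
  off-image area.
* A constant image binarizes to all background, IAM maps it to zeros,
  HISTEQ/AHE to a constant; these conventions are frozen in tests.
* Trough and valley ties break to the smallest index; the trough search
  range is the half-open central third `[floor(H/3), floor(2H/3))`.
* Angle-table CSVs with duplicate angles (hand transcription) collapse
  to the minimum trough per angle, with a warning.

## Problem sizes in the test suite

The parameter-recovery suite runs the full pipeline on 100 default
phantoms (five generator angles in {−10, −5, 0, 5, 10}, twenty seeds
each) plus ten noise-free phantoms for exact tooth counts; property
suites use small random masks, profiles and boxes against brute-force
oracles. These sizes give stable pass/fail behavior at a few minutes of
runtime on a single core while exercising every stage end to end.

## Known limitations

* Tooth counts are inferred from valley prominence when not supplied;
  heavily overlapping crowns can merge valleys and under-count.
* The half-split uses the box midline, not an anatomical axis.
* One global rotation is assumed; independent upper/lower tilt is not
  modeled.
* The trough criterion needs *some* occlusal irregularity or noise
  floor; on images whose gap is a perfect straight empty band several
  angles are exactly equivalent and the smaller-|angle| tie-break
  decides.
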