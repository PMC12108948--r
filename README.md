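# bwseg — rotation-aware single-tooth segmentation of bitewing radiographs

Bitewing radiographs show the crowns of upper and lower posterior teeth
in one frame, and caries classifiers downstream need one clean patch per
tooth (or per half-tooth, because proximal caries sits on the left/right
surfaces). Bitewings are acquired at varying tilt, so fixed cuts fail.
`bwseg` implements a projection-profile segmentation that first recovers
the tilt and then cuts:

1. **Rotation search.** For each candidate angle θ the image is rotated,
   smoothed, Otsu-binarized and eroded, and the horizontal projection
   `P(y) = #{foreground pixels in row y}` is evaluated over the central
   third of rows. The trough `min_y P(y)` is smallest when the dark
   occlusal band between the jaws is level, so the search solves
   `argmin_θ trough(θ)` on a coarse 5° grid over ±15°, refined at 1°
   steps within ±4° of the coarse winner.
2. **Jaw split** at the trough row of the best angle.
3. **Tooth split** per jaw at valleys of the vertical projection
   (local minima with topographic prominence ≥ 0.10 × profile max,
   minimum spacing 1/16 of the row width): n teeth ⇔ n − 1 separators.
4. Optional **half-tooth split** at each box midline.

The package also provides the contrast-enhancement operator bank used
around such pipelines (IAM percentile remapping, global HISTEQ, clip-
limited AHE, and their ordered chains), detection statistics (accuracy /
precision / recall from a confusion matrix, box IoU, all-point
interpolated AP and mAP, a paired t-test on IoU values), and a
deterministic synthetic bitewing phantom generator with exact ground
truth, so everything is testable without IRB-restricted clinical images.

## Worked example

```r
library(bwseg)

# a synthetic bitewing tilted by -7 degrees, with exact ground truth
ph  <- generatePhantom(phantomSpec(rotationDeg = -7, seed = 42))
res <- segmentBitewing(ph$image, halves = TRUE)
res
#> SegmentationResult 'phantom-seed42': rotation 6 deg, jaw split at row 197,
#>   8 whole teeth (24 segments total)

tab <- iouTable(res, truthToResult(ph$truth))
mean(tab$iou[tab$half == "whole"])
#> [1] 0.8267111
```

The search recovered a 6° correction for the −7° tilt (the 1° grid and
the flat trough plateau make ±1° the expected resolution), split the
jaws at row 197, and produced 8 whole teeth plus 16 halves whose boxes
overlap the generator's ground truth at a mean IoU of 0.83.

Replaying the two-stage angle selection on a previously exported
angle-to-trough table (one ships with the package):

```r
tb <- readAngleTable(system.file("extdata", "rotation_trough_table.csv",
                                 package = "bwseg"))
selectAngleFromTable(tb, coarseStep = 5, fineHalfwidth = 4)
#> $coarseBest  [1] 10
#> $coarseValue [1] 40
#> $finalBest   [1] 11
#> $finalValue  [1] 36
```

The coarse stage lands on 10° (trough 40); the fine stage finds the true
optimum one degree over, 11° with trough 36. And the evaluation module:

```r
confusionMetrics(tp = 62, fp = 1, tn = 56, fn = 1)$accuracy_pct
#> [1] "98.33%"
```

## Command line

A thin wrapper over the same functions is installed at
`inst/scripts/bwseg`:

```sh
bwseg synth --seed 42 --angle -7 --out ph.png --truth truth.json
bwseg segment ph.png --out-dir segs --halves
bwseg eval --pred segs/ph.json --truth truth.json
bwseg enhance ph.png --preset iam+histeq --out enh.png
bwseg metrics --tp 62 --fp 1 --fn 1 --tn 56
bwseg angle-table segs/ph_angles.csv
```

Crops are written as `{id}_{jaw}{index}_{half}.png` with a JSON sidecar
(`image_id`, `rotation_deg`, `jaw_split_y`, and one `{jaw, index, half,
box}` entry per segment; boxes are 0-based, half-open, in the corrected
frame) plus the evaluated angle table as CSV.

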