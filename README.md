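# preciseedge

Semi-automated segmentation of livestock photographs and fully automated
extraction of body measurements (wither height, body length, chest girth)
from the resulting masks.

## The problem

Body height, length, and heart girth are the standard manual livestock
measures used to predict weight and inform health, breeding, and marketing
decisions, but collecting them by hand is slow and stressful for the
animals. Photographing animals against a blue tarp with a calibration sign
of known size (as standardised field protocols prescribe) makes the
measurements recoverable from images — if the animal's silhouette can be
segmented precisely enough that pixel distances correspond to real
centimetres. Interactive GrabCut segmentation can deliver that precision,
but on field images it demands a lot of corrective mouse input.

This package implements **PreciseEdge**, a two-step segmentation that cuts
the required user input by removing the blue backdrop *before* GrabCut
runs:

**Step 1 — chromakey-inspired colour step.** Split the RGB image into
signed channel matrices and form the per-pixel differences `BR = B − R`
and `GR = G − R`. A pixel is *removed* (set to black) when `BR ≥ t`, where
`t` is a track-bar threshold with default 40 on the 0–120 range, *unless*
its channels are nearly equal (`|BR| ≤ 5` and `|GR| ≤ 5`), which protects
achromatic features such as the white calibration sign. The retention
matrix `bGTr` is the clamped Boolean OR of the two rules; multiplying each
channel by it suppresses the backdrop while leaving every retained pixel
bit-identical.

**Step 2 — reduced-annotation GrabCut.** A user (or the scripted annotator
that stands in for one in batch runs) draws a bounding box; pixels outside
it are sure background. Per-class Gaussian-mixture colour models are refit
each iteration from the current labelling, and the binary labelling is
solved exactly per iteration as a minimum s-t cut over the box region
(compiled Dinic solver, contrast-weighted 4-neighbour smoothness).
Refinement uses only *sure foreground* / *sure background* strokes — the
"probable" label classes of classic GrabCut are omitted. Every rasterized
stroke pixel counts as one stroke, the unit of annotation effort.

Downstream, fully automated: morphological opening/closing plus
largest-component selection, pixel→cm calibration from the minimum-area
rectangle of the segmented sign, landmark extraction (wither band, torso
band), and girth estimated as the Ramanujan perimeter of the ellipse with
the side-pose chest depth and rear-pose chest width as axes.

Because JPEG's DCT quantization visibly degrades mask edges, all images
are decoded and re-encoded as genuine PNG before processing; the package
treats lossless round-trips as a contract and tests them.

A seeded synthetic-scene generator renders backdropped animal silhouettes
with exact ground-truth masks and physical dimensions, so the whole
pipeline is testable without any image downloads.

## Worked example

```r
library(preciseedge)

spec  <- scene_spec(seed = 42, pose = "side", shadow = TRUE)
scene <- generate_scene(spec)              # 196 x 226 px, truth attached

step1 <- chroma_step(scene$image)          # blue backdrop removal
box   <- scene_bounding_box(scene)
seg   <- segment_with_robot(step1$image, scene$truth$silhouette_mask, box)
seg$strokes; seg$rounds; seg$iou
#> 0        0        1

mask  <- refine_mask(seg$mask)
sign  <- segment_sign(scene$image, scene$truth$sign_box)
scale <- extract_calibration(sign, spec$sign_cm)
scale$px_per_cm_x
#> 2

side  <- measure_side(mask, scale)
sprintf("height %.1f cm, length %.1f cm, chest depth %.1f cm",
        side$height_cm, side$length_cm, side$chest_depth_cm)
#> "height 60.0 cm, length 75.0 cm, chest depth 30.0 cm"
```

The scene was generated with a 60 cm tall, 75 cm long animal at
2 px/cm — the pipeline recovers all three measures exactly, with zero
refinement strokes after the colour step. On the same scenes the box-only
GrabCut baseline needs several hundred strokes (mostly deleting the
shadowed tarp under the belly), which is the effect the evaluation harness
quantifies: `run_stroke_experiment()` runs both pipelines over seeded
scenes, and `stroke_distribution_tests()` applies the Kolmogorov–Smirnov
normality screen and the one-sided Wilcoxon test to the stroke counts.

## Command line

A thin front end over the same functions lives at `inst/cli/preciseedge.R`:

```sh
Rscript inst/cli/preciseedge.R simulate --out runs/demo --n 5 --seed 1
Rscript inst/cli/preciseedge.R segment  --out runs/demo --manifest runs/demo/manifest.csv --mode preciseedge
Rscript inst/cli/preciseedge.R segment  --out runs/demo --manifest runs/demo/manifest.csv --mode grabcut_only
Rscript inst/cli/preciseedge.R measure  --out runs/demo --manifest runs/demo/manifest.csv \
    --segmentation runs/demo/segment_preciseedge/segmentation.csv --mode preciseedge
```

See `vignettes/preciseedge-methods.Rmd` for the model assumptions,
parameter choices, and known limitations.
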