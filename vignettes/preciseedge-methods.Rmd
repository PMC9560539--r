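---
title: "PreciseEdge: methods, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PreciseEdge: methods, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the science and the engineering decisions behind
the package: the two-step segmentation model and its assumptions, the
parameters a user might tune, what the synthetic-scene generator does and
does not emulate, and the numerical conventions adopted where the design
was genuinely open.

## The segmentation model

### Step 1: colour step

The field protocol photographs each animal against a blue tarp. In RGB,
tarp pixels have a large positive blue-minus-red difference while coat
colours (browns, greys, blacks, oranges) have `B − R` at or below zero, so
a single per-pixel statistic separates backdrop from subject. The step:

1. split the image into R, G, B channel matrices, widened to signed
   integers so channel subtraction cannot wrap around 8-bit arithmetic;
2. form difference matrices `BR = B − R` and `GR = G − R`;
3. `equivpxls`: mark pixels with `|BR| ≤ tol` and `|GR| ≤ tol`
   (default `tol = 5`) as achromatic — greys and whites such as the
   calibration sign, which must survive regardless of the threshold;
4. `bminusrslide`: mark pixels with `BR < t` for retention, where `t` is
   the track-bar threshold (default 40, range 0–120);
5. retention matrix `bGTr`: the elementwise sum of the two Boolean
   matrices clamped to `{0,1}` — a logical OR;
6. multiply each channel by `bGTr` and merge; removed pixels become
   exactly (0,0,0), retained pixels are bit-identical to the input.

Assumptions: the backdrop is blue (the statistic is blue-specific — see
Limitations), and the subject is not blue. The step is idempotent —
removed pixels become black, which is achromatic and therefore retained on
any second pass — and monotone in `t`: raising the threshold never removes
a pixel a lower setting kept. Both properties are enforced by tests.

Three conventions here were genuinely open and are resolved as follows:

* **Which channel pair accompanies `|B − R|` in the near-equality test.**
  The construction builds difference matrices `BR` and `GR`, so the
  near-equality test consumes `|G − R|`; the written description of the
  rule mentions a B-to-G comparison instead. This package follows the
  matrices actually constructed (`GR`), because that is what the
  composition of steps 2–3 can compute; the `B − G` alternative is
  available via `chroma_params(equivalence_pair = "BG")`. For truly
  achromatic pixels the two agree (if `|BR| ≤ 5` and `|GR| ≤ 5` then
  `|B − G| ≤ 10`).
* **The boundary pixel `BR = t`.** The removal interval is read as
  `[t, 255]`, inclusive at the threshold: a pixel exactly at the track-bar
  value is removed. Tests pin this down.
* **Clamping the retention sum.** The sum of the two Boolean matrices can
  reach 2 where a pixel is both achromatic and below threshold;
  multiplying intensities by 2 would corrupt them, so the matrix is
  clamped to `{0,1}`, which is the Boolean-matrix reading of the rule.

### Step 2: reduced-annotation GrabCut

The user draws one bounding box; everything outside it is sure
background. Optional refinement strokes carry only two labels — *sure
foreground* and *sure background*; the "probable" classes of classic
GrabCut are omitted. Each iteration refits one Gaussian mixture per class
(k-means hard assignment, `k = 5` components, full covariances with a
variance floor of 1 intensity² so the exactly-uniform suppressed backdrop
cannot degenerate) and solves the binary labelling exactly as a minimum
s-t cut over the box region. Smoothness terms are the standard
contrast-sensitive weights `γ · exp(−β‖z_i − z_j‖²)` on the 4-neighbour
grid with `γ = 50` and `β = 1/(2⟨‖z_i − z_j‖²⟩)` estimated inside the box.
Data terms are the capped per-class negative log-likelihoods; stroke
pixels and the outside-the-box region get effectively infinite terminal
capacities, so hard constraints always hold in the output.

Numerical conventions:

* capacities are quantized to a 1/8-intensity integer grid before the
  min-cut; integer capacities make the solver exact and fast, and the
  quantization error is negligible against `γ`-scale weights;
* the min cut is computed by a compiled Dinic solver specialised to the
  pixel grid (`src/grid_mincut.cpp`); its cut values are cross-checked
  against an independent max-flow implementation (igraph) in the tests;
  where several minimum cuts tie, the solver deterministically returns the
  source-reachable side, so batch runs are reproducible;
* iterations stop early once fewer than 0.1% of box pixels change label
  (the mixtures cannot move much after that); the default cap is 5
  iterations per refinement round, a conventional choice;
* the k-means initialisation draws from a fixed internal seed without
  disturbing the caller's RNG stream, so identical inputs give identical
  masks in any session.

### Stroke accounting

One rasterized pixel = one stroke. Polylines are rasterized with Bresenham
lines at thickness 1; duplicate pixels within one drawing action are
deduplicated, but the same pixel marked in two separate actions counts
twice, since each action adds its own coordinates. Bounding-box pixels are
not strokes.

### The scripted annotator

Batch experiments replace the human refiner with `robot_annotate()`: it
draws sure-foreground strokes along the boundaries of regions the truth
says are foreground but the mask says are background, and sure-background
strokes along false-positive regions, inset/offset 2 px from the true edge
so a stroke never asserts anything the ground truth contradicts, in events
capped at 30 px. It stops once the tolerant IoU reaches 0.98. If only
pixels within the 2 px safety margin are wrong, the inset relaxes toward 0
before the annotator gives up. These settings (stop criterion, inset,
event cap) scale the annotation-effort experiment and are exposed as
arguments.

## Automated measurement

* **Mask refinement**: morphological opening then closing with an
  elliptical (disc) kernel, default diameter 5 px, then retention of the
  largest connected component. Opening removes speckles smaller than the
  kernel; closing fills comparable holes.
* **Calibration**: the rectangular sign of known physical size is
  localised inside a user box by thresholding the blue-minus-red
  difference at half the local backdrop level. The sign is achromatic
  (`BR ≈ 0` on both its white face and dark border), so along the
  blur-mixed edge the blue difference is proportional to the mixing
  fraction and crosses half the backdrop value exactly at the 50% mix
  contour — the standard half-maximum edge-localisation convention, which
  makes the pixel-per-centimetre factors insensitive to optical blur and
  global brightness. The minimum-area rectangle (rotating calipers over
  the pixel-corner hull) then gives the pixel sides; dividing by the
  physical sides yields `px_per_cm` per axis, with a warning if the two
  factors disagree by more than 5% (a fronto-parallel sign should be
  isotropic).
* **Landmarks** (these conventions are this package's definitions — the
  upstream description of the measuring stage is "fully automated" without
  printed geometry; all band fractions are arguments):
  * *body height*: vertical extent of the silhouette within the wither
    band — the column band 20–40% of the mask width from the chest (head)
    end; the head end is detected as the lighter third of the mask, with a
    manual override;
  * *body length*: horizontal extent of the silhouette within the torso
    row band, 30–70% of the mask height;
  * *chest depth* (side pose): median top-connected vertical run over the
    rearmost quarter of the wither band — the heart-girth site just
    behind the forelegs; top-connected runs make leg columns (which run to
    the ground) distinguishable from torso columns;
  * *chest width* (rear pose): maximum horizontal contiguous run within
    the torso row band.
* **Girth**: the torso cross-section at the heart-girth site is modelled
  as an ellipse with the side-pose chest depth and rear-pose chest width
  as axes; the perimeter uses the Ramanujan approximation
  `P ≈ π[3(a+b) − √((3a+b)(a+3b))]`, which tests hold to within 0.5% of
  numerical elliptic arc length for axis ratios up to 3. This is a
  modelling choice and is validated only against synthetic truth generated
  under the same model.

Degenerate inputs error early: empty masks, signs thinner than 2 px,
non-positive girth axes. A mask touching the image border raises a
truncation warning rather than an error.

## The synthetic-scene generator

`generate_scene()` renders what the field protocol produces: a matte
animal-like silhouette (side pose: flat-backed rounded torso, head block,
two legs; rear pose: upright ellipse over two separated legs) in coat
colours over a blue backdrop filling the frame (tarp behind and beneath),
plus a white, dark-bordered calibration sign. Rendering order: solid
colours → optical blur (Gaussian, σ = 1 px, emulating focus/downsampling)
→ global brightness factor → clipped additive Gaussian noise. Ground-truth
masks and dimensions are captured *before* blur and noise, so they are
exact; consequently IoU against truth is scored with a 1 px "don't care"
band at the mask boundary, where blur makes the true edge genuinely
ambiguous.

Default study conditions: working resolution 2 px/cm (detail is measured
in centimetres, and this keeps the full segmentation loop fast enough to
run hundreds of times in the test suite; all dimensions scale linearly),
noise σ = 5 intensities, backdrop (40, 60, 200), coat (150, 100, 60).
`random_scene_spec()` samples animal dimensions from adult-goat ranges
(height 50–70 cm, length 65–90 cm, chest width 20–30 cm, depth 45–55% of
height), brightness 0.8–1.15, and jitters the colours while keeping the
protocol's chroma margins: backdrop `B − R ≥ 80`, coat `B − R ≤ −40` —
each at least one threshold-width away from the default track-bar value,
which is the separation the blue-tarp protocol is designed to provide.

The annotation-effort comparison renders scenes with the generator's
under-body shadow band enabled (`shadow = TRUE` in the experiment
harness): a darkened region of tarp under the belly is the canonical
feature of real scenes that the colour step removes outright but that a
box-only graph cut keeps — it matches the coat better than the sunlit tarp
does — and therefore the region a human must erase by hand. Without some
such realistic confuser both pipelines segment clean synthetic scenes
perfectly from the box alone and the comparison degenerates to all ties.
The generator's own default keeps shadows off, so tests of rendering
exactness stay clean.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: fur texture and coat patterns, wrinkled-tarp
shading gradients, cast shadows with soft penumbrae, partial occlusion,
perspective foreshortening of the sign, and animals whose coat is itself
bluish. The measurement-recovery numbers in particular say that the
*pipeline geometry* is unbiased under the generator's rendering model, not
that field images reach the same accuracy.

## Evaluation harness

Stroke-count distributions are screened for normality with the
Kolmogorov–Smirnov statistic using sample-estimated mean and SD (the
Lilliefors correction, via `nortest::lillie.test`; exact calibration of
this p-value is not required — it is a screen, and the tests only assert
monotone sanity). The two methods are compared with the Wilcoxon test:
rank-sum for independent samples (exact for small untied samples, midrank
normal approximation otherwise — `stats::wilcox.test`'s behaviour, which
the tests verify against full enumeration for group sizes ≤ 8), or
signed-rank on per-scene differences when the same scenes ran under both
modes, which is the design of `run_stroke_experiment()` and the package's
default comparison. The direction is fixed one-sided (two-step pipeline
needs *fewer* strokes) per the stated hypothesis. With no nonzero paired
differences the signed-rank statistic is undefined and the p-value is
reported as `NA` rather than silently passing.

Pearson correlations relate extracted to reference measures per trait,
with errors on constant vectors rather than `NA` propagation.

## Problem sizes

The packaged experiments use 30 scenes (15 side, 15 rear) for the paired
stroke comparison and 50 animals (side + rear each) for measurement
recovery, at 2 px/cm with noise σ = 5 — sizes chosen so the complete suite
and the acceptance script each run in minutes on a single core while the
statistics remain decisive. `scripts/acceptance.R --seed N` re-derives
every reported number from scratch under a new seed.

## Known limitations

* The colour statistic is blue-specific; green or grey backdrops need a
  different difference matrix (out of scope).
* Blue-ish coats violate the protocol margin and will be partially
  removed by step 1.
* Landmark conventions cannot be validated against a published geometric
  definition (none is printed for the upstream measuring stage); they are
  validated on synthetic truth only.
* The girth model assumes an elliptical cross-section; real torsos
  deviate, so absolute girth accuracy on real animals is untested here.
* One animal per frame; occlusion and multi-animal scenes are out of
  scope.
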