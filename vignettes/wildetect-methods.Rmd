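---
title: "Detecting nine-pixel animals from space: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting nine-pixel animals from space: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(wildetect)
```

## The problem

Censusing migratory ungulates at ecosystem scale requires detecting
animals that occupy at most nine pixels in 0.38–0.50 m multispectral
satellite imagery. At this size, bounding-box object detectors fail;
pixel-level semantic segmentation followed by an instance-splitting step
does not. `wildetect` implements that pipeline in three blocks — mask
generation from point labels, a Tversky-loss U-Net K-fold ensemble, and
clustering-based conversion of pixel predictions into individual animals —
plus the evaluation protocol and census products built on top.

This vignette documents the models, the tunable parameters, the numerical
choices, and what the synthetic-data experiments do and do not establish.

## Coordinates, scenes and the grid

Pixel indices are 0-based with half-open windows; the world coordinate of
a pixel refers to its **center**; a scene's `origin` is the world
coordinate of its top-left corner, with `y` decreasing down rows
(north-up). These conventions make `pixel_to_world()` /
`world_to_pixel()` round-trip exactly on integer pixel centers, which the
tests assert.

Scenes are tiled into non-overlapping 336 × 336-pixel grid cells anchored
at the scene's top-left corner (at 0.45–0.50 m resolution a cell covers
151–168 m of ground, the scale at which training and test patches are
sampled). Border cells narrower than a full patch are flagged, zero-padded
for inference, and cropped back afterwards; they are excluded from
training sampling so that no training labels are fabricated inside
padding. Network inputs are normalized by a fixed global scale — the
sensor bit-depth maximum, 2^11 − 1 for WorldView-class data — rather than
per-image statistics, keeping training and inference consistent across
scenes.

Since no GeoTIFF reader is among the package's dependencies, rasters are
stored as plain float TIFF with an ESRI world file (`.tfw`) and a JSON
sidecar for the CRS label, nodata value and bit depth. This carries the
same information (array + geotransform + CRS tag) in fully portable text
sidecars.

## Labels and masks

Each animal is annotated as one point at its center. Multi-observer label
sets are fused by majority voting: the pooled points are greedily
agglomerated, densest neighborhood first, each observer contributing at
most one (its closest) point per cluster, and clusters with at least
`min_votes` observers (default: strict majority) emit a consensus point at
the coordinate mean. Seeding is ordered by vote count, then total member
distance, then coordinates — not by input order — so fusion is invariant
to observer permutation.

Consensus points are rasterized as 3 × 3-pixel blocks (the typical animal
footprint of 3–4 × 1–3 pixels plus centroid uncertainty), clipped at patch
borders; overlapping blocks merge into one binary region. Training pairs
are augmented by horizontal flip, vertical flip and 90° rotation.

For test sampling, grid cells are stratified by animal density into four
strata. The stratification protocol specifies only that strata derive from the
mean and standard deviation of per-cell counts; the concrete breakpoints
used here are `[0, μ)`, `[μ, μ+σ)`, `[μ+σ, μ+2σ)`, `[μ+2σ, ∞)`, with the
degenerate σ = 0 case assigning every cell to `medium` (an arbitrary but
deterministic choice). Proportionate sampling uses largest-remainder
apportionment, so each stratum's quota deviates from exact proportionality
by at most one cell.

## The segmentation model

The U-Net is the canonical symmetric encoder–decoder: per level two 3 × 3
same-padded convolutions (ReLU) and 2 × 2 max pooling; a two-convolution
bottleneck; a decoder that upsamples (nearest-neighbor followed by a 3 × 3
convolution), concatenates the encoder feature map of equal resolution,
and convolves twice more; a final 1 × 1 convolution with sigmoid yields
the per-pixel animal-presence probability. Weights are He-normal
initialized; filters double per level.

Because the package depends on no deep-learning framework, the network is
implemented directly in RcppArmadillo: convolutions are im2col + one
single-precision GEMM over the whole minibatch, max-pool argmaxes and
upsampling adjoints are explicit, and the Adam optimizer and
reduce-on-plateau schedule run inside the compiled training loop. A
single integer seed drives initialization and shuffling; training is
single-threaded and bit-reproducible for a given seed and data.

Two presets are provided:

| preset  | depth | base filters | input | role |
|---------|-------|--------------|-------|------|
| default | 4     | 64           | 336 × 336 × 4 | full-scale configuration |
| small   | 3     | 8            | 96 × 96 × 4   | complete studies in minutes on one CPU core |

The small preset uses 8 base filters: on the synthetic task the 8-filter
model saturates (validation Tversky loss < 0.04 in 20 epochs) and wider
layers only multiply the GEMM cost. Classic reduced U-Nets would use 16;
nothing else in the package depends on this choice and the preset is a
one-line configuration.

### Loss

Class imbalance is extreme — animal pixels are well under 1% of a typical
patch — so plain Dice or cross-entropy collapses to the all-background
prediction. The Tversky loss

\[ L = 1 - \frac{TP + s}{TP + \alpha\,FP + \beta\,FN + s}, \qquad
   \alpha + \beta = 1, \]

with soft counts \(TP = \sum p\,t\), \(FP = \sum p\,(1-t)\),
\(FN=\sum(1-p)\,t\), lets the false-negative weight β dominate. The
package names the parameters `fp_weight` and `fn_weight` (rather than α/β,
whose assignment to error types is often stated inconsistently in the
literature); defaults are `fn_weight = 0.9`, `fp_weight = 0.1` — the
setting that prioritizes recall of rare animal pixels. At (0.5, 0.5) the
loss reduces algebraically to Dice, which the tests verify numerically.
The smoothing constant `s` defaults to 1, the standard stabilizer for
empty masks. The loss is computed per sample and averaged over the batch;
its gradient uses the closed form
\(\partial L/\partial p_i = -(t_i D - N\,(\,t_i + \alpha(1-t_i) - \beta
t_i\,))/D^2\).

The right asymmetry depends on the data and the training budget, which is
why the package ships the sensitivity analysis as a utility
(`sweep_tversky_weights()`): one base model per candidate `fn_weight`,
each scored on validation tiles through the full detection chain. On the
synthetic scenes under the short 20-epoch schedule the sweep favors
symmetric weights — `fn_weight = 0.5`, i.e. the Dice special case
(validation F1 ≈ 0.94–0.97, versus ≈ 0.78 at 0.9): with few optimizer
steps the extreme 0.9 asymmetry reaches full recall early but never
learns to suppress confuser objects, while weights below 0.5 start to
risk the collapse described next. The full-scale default stays at 0.9,
the value appropriate for the much longer schedule and the <1 %
real-data imbalance.

Tversky training under heavy imbalance has a genuine failure mode the
package guards against: an **all-background local minimum**. When the
early "suppress false positives" phase overshoots, every logit saturates
deeply negative, `p(1−p)` vanishes, and the rare positives can never pull
the network back — the validation loss flatlines at the analytic
all-background value `1 − s/(β·Σt + s)`. Whether a run falls in is
seed-dependent and more likely the smaller `fn_weight` is. (Initializing
the output bias at the class-prior logit, the standard trick for
cross-entropy detectors, makes this strictly worse for a ratio loss:
starting near zero probability removes the soft-TP mass that carries the
positive gradient, so the uncommitted 0.5 start is kept.)
The package uses two complementary defenses, both driven by validation
quantities only:

* **Loss-weight warmup** (`warmup_epochs`, `warmup_fn_weight`): the first
  few epochs train with recall-heavy weights (0.9), which reliably pull
  the network away from the all-background solution — the very effect
  that motivates the high-β setting in the first place — before
  switching to the target weights. Validation loss and checkpoint
  selection always use the target weights, so the warmup changes the
  trajectory, not the objective. The packaged studies use a 5-epoch
  warmup.
* **A convergence guard**: `train_base_model()` compares its best
  validation loss against the all-background baseline — every failure
  mode (all-background, all-foreground, unstructured output) stays near
  it, while converged models sit an order of magnitude below — aborts a
  run still at the baseline by epoch 6, and restarts with a derived seed
  (a bounded number of times, with a warning). Runs that learn are
  completely unaffected.

Robust members matter doubly for the ensemble: a non-converged member's
map would be min–max rescaled per patch before fusion, amplifying its
noise into structured false positives.

### Schedule

Defaults mirror the full-scale recipe: Adam at 1 × 10⁻⁴, learning rate
multiplied by 0.33 after 20 epochs without validation improvement, batch
size 12, 120 epochs, dropout 0, and the checkpoint with the smallest
validation loss across epochs is kept. For the small-preset synthetic
studies the package uses 20 epochs at 1 × 10⁻³: the short schedule has
~45 optimizer steps per epoch, and the higher rate is the standard
adjustment when the step budget shrinks by an order of magnitude.

## The ensemble

The training set is split into K folds (K = 10 at full scale; K = 3 in
the packaged studies); base model *i* trains on all folds but *i* and is
checkpoint-selected on fold *i*. At inference each member's probability
map is min–max rescaled to [0, 1] — but only when its maximum exceeds
0.05; essentially-empty maps are left untouched so that noise in
animal-free patches is not amplified into false structure. The rescale is
applied per inference window (the natural reading of map-wise rescaling;
a scene-level variant would only differ when a scene's dynamic range is
concentrated in a few patches). A constant map above the gate is zeroed
with a warning: a feature-free map carries no detection evidence. The
fused prediction is the element-wise mean of the member maps.

## From pixels to individuals

The fused map is binarized at 0.5 with an inclusive threshold (ties are
positive — one convention has to be picked and documented). Connected
components use 8-connectivity by default: diagonal 3–4-pixel bodies would
fragment under 4-connectivity. Each segment of *n* pixels becomes
⌈*n*/9⌉ individuals — nine pixels being one animal's footprint — located
at the centroids of a seeded K-means (10 restarts, best inertia) on the
segment's pixel coordinates. Tests verify against exhaustive enumeration
that best-of-restarts K-means attains the optimal within-cluster sum of
squares on small segments.

Inference tiling is overlap-free, matching the training patch layout; an
animal straddling a tile seam can therefore be reported by both tiles (a
documented, test-covered behavior bounded by one extra point per seam
crossing).

## Evaluation protocol

Matching is one-to-one within a radius of √2 × pixel size — the ground
length of one pixel diagonal, 0.71 m at 0.5 m resolution — absorbing the
one-pixel centroid shifts expected when an animal's segment is not a
perfect 3 × 3 square. The comparison uses the full-precision radius
(0.7071…), treating the printed 0.71 as a rounded display value, and an
inclusive boundary. Candidate pairs are processed globally by increasing
distance with stable index tie-breaks: deterministic, order-independent,
and equal to the optimal assignment whenever animals are separated by more
than twice the radius (verified against a maximum-cardinality bipartite
matching oracle; on arbitrary instances greedy is provably a lower bound).

Precision, recall and F1 follow the standard definitions with 0/0 defined
as 0. Precision–recall curves sweep thresholds 0.05–0.95 in steps of 0.05
through the *full* post-processing chain, append the conventional
endpoints (recall 0, precision 1) and (1, 0) for thresholds 1 and 0, and
integrate by the composite trapezoidal rule over recall-sorted points.

Census counts from repeated training runs get a t-based 95% interval,
`t(0.975, n−1)·sd/√n` — at n = 5 runs the t quantile (2.78) matters; a
normal-approximation flag exists for comparison. Hotspot rasters count
points within a 500 m radius of each 100 m cell center and divide by the
neighborhood area (π·0.25 km²); the km² histogram partitions the extent
into 1 km cells anchored at its top-left corner, so every in-extent point
lands in exactly one cell and the histogram mass conserves the point count
exactly.

## The synthetic scenes

The generator emulates the imaging conditions the pipeline targets:

* 11-bit digital numbers in four bands (R, G, B, NIR ≈ 1100/1050/950/1500
  DN baselines), a low-frequency background texture (bilinearly upsampled
  Gaussian field, 20 m correlation length, ±5 %) plus ~1 % pixel noise —
  the normalization path divides by 2047 exactly as for sensor data;
* animals as rotated-ellipse footprints 3–4 px long and 1–3 px wide with
  1–2 darker central pixels, at a default contrast of 0.45 (clearly
  visible, "high-contrast" animals) — ground truth is the center pixel;
* aggregation patterns: `scattered` (uniform with a 5-pixel Chebyshev
  separation, so 3 × 3 footprints never merge), `clustered`
  (parent–offspring Thomas process), and `linear` (jittered placement
  along a random polyline, mimicking trail-following herds);
* confusers that are larger or differently shaped than animals: dark
  round bushes (NIR-bright), elongated mound shadows, bright road strips,
  dark curvy rivers;
* reference pairs — two scenes with identical background and confusers,
  animals in only one — emulating the cross-referencing workflow used to
  separate animals from static look-alikes during labeling.

What the synthetic experiments establish: that the implementation of every
stage is correct and that the ensemble learns and recovers individuals
under the stated appearance model. What they do not establish: performance
on real sensor data — real scenes have pan-sharpening artifacts, terrain
shadows, atmospheric variation, mixed herds and observer label noise that
the generator does not model. Synthetic accuracies are therefore
implementation checks, not forecasts of survey accuracy.

An oracle probability map (3 × 3 blocks of probability 1 on background 0,
optionally with uniform noise) isolates post-processing and evaluation
from learning entirely: at zero noise the pipeline must recover every
animal exactly, and does.

## The packaged end-to-end study

The acceptance study trains the small preset as a K = 3 ensemble on 200
synthetic 96 × 96 tiles (Poisson-distributed animal counts, mean 7;
2 bushes and 1 mound shadow per tile as confusers), 20 epochs at
1 × 10⁻³ with the sweep-selected symmetric Tversky weights and a 5-epoch
recall-heavy warmup (see above), and evaluates on 50 held-out tiles:
pooled F1 ≥ 0.85 at the fixed seed, with the fused ensemble's PR-AUC at
least the mean of its members'. Augmentation is off in this study: the held-out tiles are drawn
from the same generative distribution, so flip/rotation variants add
compute without testing anything the study measures (augmentation is
exercised by its own invariance tests and remains the default for real
training). Problem sizes — 200/50 tiles, K = 3, 20 epochs — were chosen so
the whole study, training included, completes in about five minutes on a
single CPU core.

## Known limitations

* Tile-seam duplication under overlap-free tiling (an overlap+crop
  inference mode is the natural extension).
* The ceiling rule fixes the per-animal footprint at 9 pixels; very tight
  herds at coarser resolutions would need a resolution-dependent size.
* The fusion radius and K-means splitting assume approximately isotropic
  herd geometry within a segment.
* Species of similar size cannot be discriminated at 0.4–0.5 m resolution;
  detections are "wildebeest-like animals".
* The compiled U-Net targets small presets on CPUs; it is not a
  general-purpose training framework (no GPU, no arbitrary architectures).
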