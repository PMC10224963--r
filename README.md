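# wildetect

Locating and counting very small animals — wildebeest-sized ungulates that
occupy at most nine pixels — in sub-meter multispectral satellite imagery.

Migratory herds in open savanna systems can only be censused at ecosystem
scale from above. At 0.38–0.50 m ground sample distance an individual
wildebeest is a 3–4 × 1–3 pixel gray-brown blob with one or two darker
central pixels: far too small for bounding-box object detectors, but
resolvable by pixel-level semantic segmentation. `wildetect` implements the
full pipeline from point annotations to census products:

1. **Annotation & masks.** Multi-observer point labels are fused by
   majority voting (`fuse_annotations()`) and rasterized into 3×3-pixel
   binary masks (`rasterize_points()`); scenes are tiled on a 336-pixel
   grid (≈150–170 m cells depending on resolution).
2. **Segmentation ensemble.** A U-Net (compiled in
   RcppArmadillo; no external deep-learning framework) is trained with the
   Tversky loss

   `L = 1 − (TP + s) / (TP + α·FP + β·FN + s)`,  α + β = 1,

   with soft counts TP = Σ p·t, FP = Σ p·(1−t), FN = Σ (1−p)·t. The
   default weights α = 0.1 (false positives) and β = 0.9 (false negatives)
   counter the extreme class imbalance (<1 % animal pixels). K-fold
   splitting (K = 10 by default) yields K base models whose probability
   maps are min–max rescaled (when max > 0.05) and averaged
   (`train_ensemble()`, `fuse_probmaps()`).
3. **Individuals.** The fused map is thresholded at 0.5, connected
   components are extracted (8-connectivity), and each segment of *n*
   pixels is split into ⌈*n*/9⌉ individuals by seeded K-means on its pixel
   coordinates (`detect_scene()`).
4. **Evaluation.** Detections match references one-to-one within
   √2 × pixel size (0.71 m at 0.5 m resolution); precision, recall, F1,
   and precision–recall curves with composite-trapezoid AUC
   (`match_points()`, `pr_curve()`); leave-one-year-out transfer splits
   (`transfer_protocol()`).
5. **Census products.** Per-scene counts with t-based 95 % confidence
   intervals over repeated runs (`count_with_ci()`), point-density hotspot
   rasters (100 m cells, 500 m radius) and count-per-km² histograms
   (`point_density()`, `density_histogram()`).

Because very-fine-resolution commercial imagery cannot be redistributed,
the package ships a seeded synthetic-scene generator (`generate_scene()`)
that emulates 11-bit WorldView-class radiometry, the stated animal
appearance, scattered/linear/clustered herd aggregation, and confuser
objects (bushes, termite-mound shadows, roads, rivers). Every stage of the
pipeline is exercised end-to-end on these scenes.

## Worked example

```r
library(wildetect)

# a 96 x 96 px synthetic scene with 12 animals and ground truth
sim <- generate_scene(scene_spec(width_px = 96, height_px = 96,
                                 n_animals = 12, seed = 42))

# oracle probability map (perfect segmentation) -> detection -> scoring
p   <- generate_oracle_probmap(sim$truth, geotransform(sim$scene), c(96, 96))
det <- detect_scene(p, sim$scene)
m   <- match_points(det, sim$truth, matching_radius(0.5))
compute_metrics(m)[c("precision", "recall", "f1")]
#> $precision
#> [1] 1
#> $recall
#> [1] 1
#> $f1
#> [1] 1

count_with_ci(c(100, 104, 98, 101, 97))
#> $mean_count  [1] 100
#> $half_width  [1] 3.40 (t(0.975, 4) * sd / sqrt(5))
```

Training a real (small-preset) ensemble on synthetic tiles:

```r
tiles <- lapply(1:200, function(s) {
  sim <- generate_scene(scene_spec(width_px = 96, height_px = 96,
                                   n_animals = 7, seed = s))
  list(image = normalize_patch(sim$scene),
       mask  = rasterize_points(sim$truth, geotransform(sim$scene), c(96, 96)))
})
ens <- train_ensemble(tiles, unet_config_small(),
                      train_config(epochs = 20, learning_rate = 1e-3),
                      ensemble_config(K = 3, seed = 1))
```

A command-line wrapper with `simulate`, `prepare`, `train`, `predict`,
`evaluate`, `density` and `count` subcommands is installed at
`inst/cli/wildetect.R`; each run writes a JSON manifest so outputs are
regenerable from the manifest alone.

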