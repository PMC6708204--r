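# aslic — adaptive superpixel segmentation of glioma in T2-weighted MRI

`aslic` is an R package for automatic 2D glioma segmentation on
T2-weighted MRI slices, built for researchers who need reproducible,
training-light tumor masks (and a fully synthetic test bed to validate the
machinery without any patient data).

The pipeline classifies **superpixels** rather than pixels:

1. **SLIC0 superpixels with an adaptive K.** SLIC clusters pixels with the
   joint distance `D = sqrt(d_c^2 + (d_s/S)^2 C^2)` (gray distance `d_c`,
   spatial distance `d_s`, grid interval `S = sqrt(N/K)`); SLIC0 sets the
   compactness `C` per cluster automatically. The remaining hyperparameter
   — the superpixel count `K` — is predicted per slice by a 5-tree random
   forest from two hemispheric-asymmetry descriptors:
   - **TAR** (tumor area ratio): the slice is midline-aligned, divided
     into 16 × 16 cells of 15 × 15 px, and each cell is correlated with
     its mirror cell; `TAR = n/256` counts cells with Pearson `r < 0.81`.
   - **TC** (tumor boundary complexity): boundary-pixel count over
     area-pixel count of the flagged-cell union,
     `TC = N(edge)/N(area)`.
   Training labels for `K` come from a grid search over
   `K = 10, 20, ..., 450` scored by `Dice(A, B) = 2|A∩B|/(|A|+|B|)`,
   where `A` merges superpixels overlapping the ground truth by > 90%.
2. **69 features per superpixel**: 17 intensity statistics, 13 Haralick
   features on each of the gray-level / Roberts-gradient / Prewitt
   co-occurrence matrices (4 directions × 4 quantization levels,
   averaged), mean curvature, and 12 fractal features (area, brightness,
   box-counting dimension over 4 multi-level-Otsu channels).
3. **RBF-SVM classification** of superpixels into tumor / non-tumor
   (z-scored features, 5-fold CV over a log grid of (C, γ), inverse-
   frequency class weights); the union of tumor superpixels is the mask,
   evaluated by Dice, Hausdorff distance, sensitivity and specificity.

A synthetic phantom generator (`generate_tumor_phantom()`) produces
240 × 240, 12-bit, mirror-symmetric head phantoms with seeded irregular
tumor blobs and exact ground-truth masks, so the entire pipeline is
testable end to end with no external data.

## Worked example

Train on 16 synthetic phantoms, segment 4 held-out phantoms:

```r
library(aslic)
pairs <- lapply(1:20, function(i) {
  p <- generate_tumor_phantom(phantom_spec(seed = 1000 + i,
                                           tumor_radius = 12 + (i %% 7) * 2,
                                           irregularity = 0.1 + (i %% 5) * 0.07))
  list(image = p$image, mask = p$mask)
})
cfg <- default_config()
models <- cmd_train_all(pairs, cfg)              # K forest + SVM, 16/4 split
test_ix <- which(models$split$role == "test")
metrics <- do.call(rbind, lapply(test_ix, function(i)
  cmd_segment(pairs[[i]]$image, models$k_model, models$svm_model, cfg,
              gt = pairs[[i]]$mask)$metrics))
summarize_cohort(metrics)
```

which prints (4 held-out phantoms):

```
  group n dice_mean     dice_sd  hd_mean    hd_sd sensitivity_mean
1   ALL 4 0.9976982 0.004283764 1.707738 2.788938              100
  sensitivity_sd specificity_mean specificity_sd
1              0         99.98752      0.0237992
```

`dice_mean` is the overlap with the ground truth (1 = perfect);
`hd_mean` is the worst boundary deviation in pixels; sensitivity is the
percentage of tumor pixels recovered and specificity the percentage of
non-tumor pixels correctly left out (the background-inclusive denominator
makes values near 99.9% typical). On a single slice,
`cmd_segment()` also reports the predicted `K` and the (TAR, TC)
descriptor.

A thin command-line wrapper over the same functions lives at
`inst/cli/aslic.R`:

```sh
Rscript inst/cli/aslic.R make-fixtures --out fixtures --n 20 --seed 1
Rscript inst/cli/aslic.R train-all --data fixtures --out models
Rscript inst/cli/aslic.R segment --image fixtures/slice_001.tif \
    --kmodel models/k_model.json --svm models/svm_model.json --out mask.png
```

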