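# lesionpipe

Classical, fully inspectable analysis of dermoscopic skin-lesion images in R:
from raw RGB image to a benign/malignant call, with every intermediate stage
exposed as a tested function.

Dermoscopy images of pigmented lesions are contaminated by hairs, uneven
exposure, and pixel noise. Rather than classifying raw pixels with a large
network, this package measures the lesion: it cleans the image, isolates the
lesion region, computes 14 geometric and 6 textural features, selects the 10
most informative by principal-component loadings, and classifies with a
compact dense network (64/32/16 hidden units, two-class softmax) trained by
explicit backpropagation under any of five optimizers (SGD, RMSprop, Adam,
Adamax, Nadam). It is aimed at researchers who want a pipeline whose every
step can be checked against a brute-force definition.

The stages, in order:

1. **Hair removal** — grayscale (BT.601), BlackHat transform
   `closing(A, B) − A` with a 23 × 23 structuring element, binary threshold,
   and diffusion inpainting of the detected strokes.
2. **Background handling** — rolling-ball background estimation (grayscale
   opening by a spherical cap) for illumination QC, and large-window
   closing + quadratic-surface flattening before thresholding.
3. **Denoising** — non-local means, mean, median, Gaussian, and conservative
   smoothing filters; quality scored by PSNR, MAE, SSIM, histogram distance,
   and Dice; a rank-sum procedure picks the best filter × enhancement
   combination (histogram equalization vs piecewise linear transform).
4. **Segmentation** — Otsu thresholding, border-component removal, largest
   connected component; binary erosion/dilation/morphological gradient.
5. **Features** — area, perimeter, axis lengths, solidity, circularity
   (`4π·area / convex_perimeter²`), extent, equivalent diameter
   (`√(4·area/π)`), convex/filled/scratched areas; mean, SD, Shannon and
   GLCM entropies, skewness, kurtosis over the masked region.
6. **Reduction & classification** — min–max scaling (eq. `(x − x_min) /
   (x_max − x_min)`), PCA, feature ranking by summed absolute loadings of the
   first five components, near-miss class balancing, stratified
   80/10-of-train/20 splitting, and the optimizer-grid evaluation emitting
   accuracy, SEN, SPE, FPR, FNR, FDR, MSE, RMSE, and log-loss per row.

A synthetic-data module generates dermoscopy-like images (elliptical lesion,
Bézier hair strokes, radial vignette, Gaussian noise) with exact ground-truth
lesion and hair masks, plus two-class Gaussian feature tables, so the entire
pipeline runs and is scored without downloading anything.

## Worked example

```r
library(lesionpipe)

spec  <- lesion_image_spec(seed = 7)        # 224 x 224, 5 hairs, noise sd 4
scene <- generate_lesion_image(spec)        # image + ground-truth masks

hr  <- remove_hairs(scene$image)
dice(hr$mask, scene$hair_mask)              # 0.533  (detected vs true hairs)

roi <- extract_roi(hr$image)
dice(roi$mask, scene$lesion_mask)           # 0.989  (lesion recovered)

geometric_features(roi$mask, hr$mask)[c("area", "circularity", "ls_ratio")]
#>        area circularity    ls_ratio
#>    4135.000       0.948       1.462
```

The hair Dice of 0.53 reflects that the detected mask is a few pixels wider
than the true strokes (the BlackHat response includes a halo); the lesion ROI
overlaps ground truth almost perfectly. The full pipeline on a 40-per-class
synthetic corpus:

```r
cfg <- pipeline_config(list(
  seed = 1, synthetic = list(n_per_class = 40),
  training = list(optimizers = "adamax", learning_rates = 0.006,
                  epochs = 80)))
res <- run_full(cfg)
res$selected_features
#>  [1] "solidity" "glcm_entropy" "scratched_area_sq_microns" "scratched_area"
#>  [5] "extent" "mean" "ls_ratio" "circularity" "kurtosis" "skewness"
res$results[c("Optimizer", "LR", "T_Acc", "SEN", "SPE", "MSE", "RMSE", "LL")]
#>   Optimizer    LR T_Acc SEN SPE MSE RMSE     LL
#> 1    adamax 0.006   100 100 100   0    0 0.0469
```

The two synthetic classes differ in lesion size and tone, so the selected
shape/texture features separate them completely; `T_Acc` is the held-out test
accuracy in percent, `MSE = 100 − T_Acc` by construction on hard predictions,
and `LL` is the 1e-15-clipped log-loss. A thin command-line front end over
the same functions ships at `inst/cli/lesionpipe.R`
(`synth`, `preprocess`, `features`, `full` subcommands).

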