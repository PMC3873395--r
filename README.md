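# cooctex

Texture image classification built around the gray-level co-occurrence
matrix (GLCM), for researchers who classify textured images — histology
sections, electron-microscopy fields, fluorescent cell images, or any
raster where the class signal lives in local gray-level statistics rather
than in shapes or edges.

## What it computes

For an image quantized to `N = 256` gray levels, the co-occurrence matrix
at displacement distance `d` and orientation `θ` is the histogram

```
C[i, j] = # { pixel pairs (p, q) at offset (d, θ) with v(p) = i, v(q) = j }
```

accumulated symmetrically (each pair counted in both orders) over
`d ∈ {1, 3}` and `θ ∈ {0°, 45°, 90°, 135°}` — eight matrices per image.
From these the package extracts five descriptor families:

- **HR** — the 13 classical Haralick statistics (energy, correlation,
  inertia, entropy, inverse difference moment, sum/difference averages,
  variances and entropies, two information measures of correlation) of
  each matrix, concatenated to a 104-vector;
- **GR** — 11 gray-level run-length indicators (SRE, LRE, GLN, RLN, RP,
  LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE) computed *on the co-occurrence
  matrix itself* after log-quantizing its counts to 16 levels, over four
  run directions (352 values);
- **SH** — the matrix read as a 3D surface: binary level curves at heights
  1, 3, …, 19, the largest blob per level fitted by its moment-equivalent
  ellipse, and nine features describing the evolution of the series;
- **CU** — area-ratio curvature (circular masks of radius 3, 5, 7) along
  the level-curve contours at heights 1, 4, …, 13, quantized into
  8-bin histograms;
- **LD** — the matrix projected directly onto a PCA subspace retaining
  99% of the training variance.

Each family can additionally be extracted from **subwindows** of the
matrix (`*sub`: the four 128×128 quadrants for HR/GR/CU/LD, twelve fixed
overlapping windows for SH) and at **multiple scales** (`*sca`: the
original image plus Gaussian-smoothed versions, kernel sizes 3 and 5,
σ = 1). Every (descriptor, window, scale) panel trains its own SVM
(kernel and parameters chosen by inner 5-fold cross-validation); panel
scores are z-normalized (mean 0, sd 1) and fused by weighted sum —
including the cross-family ensembles `SUM2` (HRsca + GRsca), `WS2`
(2 : 1), `W2` and `W3` (SUM2 and SHsca at 2 : 1 and 3 : 1). Performance
is reported as one-vs-all AUC averaged over stratified 5-fold
cross-validation, with all fitting (SVMs, score normalizers, PCA bases)
confined to the training folds.

A synthetic-texture module (separable AR(1) random fields with
controllable lag-1 autocorrelation ρ, stripes, checkerboards, blob
fields, and analytic Gaussian-bump matrices with closed-form level-set
ellipses) makes the whole pipeline testable without any image downloads.

## Worked example

```r
library(cooctex)

img <- makeImage(textureSpec(1, "correlated_noise", size = c(64, 64),
                             seed = 7, rho = 0.8))
img
#> GrayImage: 64 x 64, 256 gray levels, range [0, 255]

s <- glcmSet(img)
s
#> GlcmSet: 8 matrices (d = {1,3}, theta = {0,45,90,135}), 256 gray levels

round(haralick13(glcmMatrices(s)[["d1_t0"]]), 4)[
  c("energy", "correlation", "inertia", "entropy", "idm")]
#>      energy correlation     inertia     entropy         idm
#>      0.0002      0.7730    818.1959     12.4519      0.0433
```

The Haralick correlation 0.773 reflects the strong lag-1 autocorrelation
(ρ = 0.8) of the generated field; energy is tiny and entropy large
because the 256×256 histogram of a noisy texture is spread over many
cells. A full cross-validated experiment on a two-class problem
(ρ = 0.2 vs ρ = 0.8, ten images per class):

```r
ds <- makeDataset(10, list(
  low  = textureSpec(1, "correlated_noise", size = c(32, 32), rho = 0.2),
  high = textureSpec(2, "correlated_noise", size = c(32, 32), rho = 0.8)),
  seed = 1)
res <- runExperiment(ds$images, ds$labels, "HR", seed = 1)
res$auc
#> [1] 1
res$aucPerFold
#> [1] 1 1 1 1 1
```

The two correlation levels separate perfectly — the Haralick correlation
statistic alone differs by ~0.6 between the classes.

## Command line

A thin wrapper over the same functions lives in `inst/cli/cooctex.R`:

```sh
Rscript inst/cli/cooctex.R synth    --out data --n 50 --size 64 --seed 1
Rscript inst/cli/cooctex.R glcm     data/img0001.png --out glcms --d 1,3
Rscript inst/cli/cooctex.R extract  --manifest data/manifest.csv --method HR --out feats
Rscript inst/cli/cooctex.R evaluate --manifest data/manifest.csv --method HRsub --out results
```

Configuration can also be given as a YAML file (`--config run.yaml`, see
`runConfig()` / `writeRunConfig()`).

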