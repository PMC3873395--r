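---
title: "Texture descriptors from the co-occurrence matrix: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Texture descriptors from the co-occurrence matrix}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cooctex)
```

## The model

All descriptors in this package start from the gray-level co-occurrence
matrix (GLCM). For an image quantized to $N = 256$ levels and a
displacement given by a distance $d$ and an orientation $\theta$, the
matrix counts gray-level transitions between pixel pairs:
$C[i,j]$ is the number of pairs $(p, q)$ at that offset with levels
$v(p) = i$ and $v(q) = j$. Four orientations (horizontal, two diagonals,
vertical; offsets $(0,d)$, $(-d,d)$, $(-d,0)$, $(-d,-d)$ in row/column
coordinates) and two distances ($d \in \{1, 3\}$) give eight matrices per
image. The premise shared by every descriptor family is that the class
signal of a texture is contained in the *shape of this histogram* — its
concentration near the diagonal, its spread, and its level-set geometry.

### Symmetric accumulation

Each pixel pair is counted in both orders, so every matrix is symmetric
and its total equals twice the number of valid pairs. Symmetry is what the
Haralick statistics implicitly assume (equal marginals), and it is the
only convention under which diagonal subwindow pairs such as the
(0,0)–(127,127) and (128,128)–(255,255) quadrants carry mirrored
information. One consequence worth knowing: run-length features computed
on the *full* matrix are identical for run directions $0°$ and $90°$ (and
for $45°$/$135°$), because row scans of a symmetric matrix are column
scans of its transpose. The redundancy disappears on the off-diagonal
quadrant windows, which are transposes of each other rather than
symmetric themselves.

### Windows and scales

Descriptors are extracted from the whole matrix and from rectangular
subwindows of it, specified in inclusive 0-based bin coordinates (so
(0,0)–(127,127) spans 128 bins). For the Haralick, run-length, curvature
and subspace families the `*sub` variants use the whole matrix plus the
four 128×128 quadrants: once the two diagonal quadrants are in the set,
the two off-diagonal quadrants are the only symmetric completion, and on
a symmetric matrix they carry the transposed halves of the off-diagonal
mass. The SHAPE family uses its own fixed list of twelve overlapping
windows (`shapeWindows()`), a mix of quadrant-, half- and center-scale
regions along the diagonal.

The `*sca` variants add two smoothed versions of the image, filtered with
2D symmetric Gaussian kernels of size $k = 3$ and $k = 5$ (σ = 1 pixel,
kernel normalized to unit sum). Borders are handled by edge replication —
zero padding would manufacture spurious dark-to-bright transitions in the
GLCM — and the filtered images are rounded back to integer levels,
because the co-occurrence matrix is a histogram over discrete levels.
RGB inputs collapse by the standard luminance weights 0.299/0.587/0.114;
16-bit inputs rescale linearly by the full bit-depth range, not the
observed maximum, so that an 8-bit image passes through unchanged.

## Descriptor families

### Haralick statistics (HR)

The 13 classical statistics are computed from the matrix normalized to a
joint probability table, with base-2 logarithms and the
$0 \log 0 := 0$ convention. Two definitions in the literature are
ambiguous and are fixed here as constants: *sum variance* is the variance
of the sum distribution $p_{x+y}$ about its own mean (the sum average),
and *difference variance* is the variance of $p_{|x-y|}$ about its mean.
Degenerate matrices (all mass at one level, hence zero marginal variance)
return correlation 0 and IMC1 0 with a warning instead of NaN, which
keeps subwindow pipelines total: a window containing no counts at all
yields a documented all-zero 13-vector. IMC2's argument is clamped at
zero before the square root to absorb floating-point negatives.

### Run-length features on the GLCM (GR)

Eleven run-length indicators are computed on the co-occurrence matrix
*treated as an image*. Raw GLCM counts are far too heavy-tailed to be run
over directly, and no published rule fixes the mapping from counts to
run-able levels; the package uses logarithmic compression to 16 levels,
$\ell = \lfloor 16 \cdot \log(1+c)/\log(1+c_{\max}) \rfloor$ (clipped),
exposed as the `rlLevels` option. Log scaling preserves the structure of
the low-count tail where most of the matrix lives; 16 levels keeps the
run matrix dense enough that the nonuniformity statistics do not
degenerate. Gray levels are 0-based, so the low/high gray-level emphasis
family weights by $(i+1)^{\pm 2}$ to avoid division by zero at level 0 —
a documented convention, not a claim about the original formulation.
Diagonal runs enumerate every diagonal including the length-1 corners.

### Level-curve shape (SH)

The matrix is read as a 3D surface and sliced with horizontal planes at
heights 1, 3, …, 19 applied to *raw* counts (`counts > h`, strict).
The counts are deliberately not normalized: the low region of the surface
is stable while the peak height fluctuates with image noise, so
normalizing by the maximum would inject that noise into every level.
Connected components use 8-connectivity; the largest component (ties
broken by smallest linear pixel index) is summarized by its
moment-equivalent ellipse — axis lengths $4\sqrt{\lambda_i}$ of the
coordinate covariance eigenvalues, which recovers the diameter of a
rasterized disc, and an axial orientation in $[-\pi/2, \pi/2)$.

The per-level ellipse series is condensed into nine features. There is
no single canonical nine-feature set for level-curve evolution in the
literature, so this package fixes its own deterministic set: (1–2) slope and intercept of the least-squares fit of main-blob
area against height; (3–4) mean and slope of eccentricity against height;
(5) circular mean of the (period-$\pi$) orientations; (6) total centroid
path length across consecutive non-empty levels; (7) number of non-empty
levels; (8) mean blob count per level; (9) area ratio between the lowest
and highest non-empty levels. These capture growth, anisotropy, drift and
fragmentation of the level curves; they are not numerically comparable to
other level-curve feature sets.

### Curvature histograms (CU)

At heights 1, 4, …, 13, the main blob's contour (blob pixels with a
4-neighbor outside the blob; the matrix border counts as outside) is
traversed, and at each contour point the fraction of a circular mask of
radius $r \in \{3, 5, 7\}$ covered by the blob is measured: ~0.5 on a
straight edge, smaller on convex contours, larger on concave ones.
Contour pixels straddle the true sub-pixel boundary, so they contribute
with weight $1/2$; without this midpoint correction a straight edge reads
$0.5 + (2r+1)/(2 \cdot \text{mask area})$ — about 0.62 at $r = 3$ — and
the estimator would be biased at exactly the radii that matter on a
256×256 matrix. Per level and radius the measures are quantized into 8
equal-width bins on $[0,1]$ and normalized to sum 1 (all-zero when a
level is empty). Radii and bin count are configurable; the defaults suit
the 256×256 matrix scale.

### Direct subspace projection (LD)

Each matrix (optionally a window of it) is flattened and projected onto a
PCA basis retaining 99% of the training variance — the smallest leading
set of components whose cumulative explained variance reaches the
threshold. Matrices are count-normalized to probabilities before
flattening so that image size does not dominate the variance; without
it, the first component would mostly encode how many pixel pairs each
source image contributed.
One subspace is fitted per (d, θ, window, scale) slot and the projections
are concatenated, matching per-matrix extraction followed by
concatenation; projecting first and concatenating after is the only
reading consistent with extracting features "for each" distance and
orientation. Subspace models are always fitted inside the training fold.
A memory guard (default 2 GB) refuses configurations whose flattened
training matrices would not fit, with a clear error naming the budget.

## Classification and fusion

Every (descriptor family, window, scale) panel trains its own SVM.
Kernel (linear, polynomial degree 2–3, RBF with
$\gamma \in 2^{-5..3}$) and cost $C \in \{0.01, 0.1, 1, 10, 100\}$ are
chosen by mean one-vs-all AUC over stratified inner 5-fold
cross-validation of the training partition; ties resolve to the earliest
grid entry, making selection deterministic. Features are standardized
with training statistics (constant columns zeroed); multi-class problems
use one-vs-all SVMs whose decision sign is oriented by the training class
means, because the sign convention of the underlying solver depends on
label order.

Scores are z-normalized per class column — population standard
deviation, constant columns to zero, statistics always estimated on the
training fold and applied to the test fold — and fused by weighted sum.
The ensemble weighting rules are: `*sub` weights the whole-matrix panel
4 and each quadrant 1 (SHAPE: first five windows 1, remaining eight
0.5); `*sca` for HR/GR/CU/LD weights the five original-image panels 4
and the ten filtered-image panels 1, the scale rule replacing the window
rule; SHsca multiplies the window weight by the scale weight, the only
rule consistent with both of the above. Cross-family ensembles (`SUM2`,
`WS2`, `W2`, `W3`) re-normalize each member's fused panel before the
second-level weighted sum, so that a member with many panels does not
dominate by scale alone. Normalization is applied uniformly inside
within-family sums too: it matters only for cross-descriptor fusion,
where score scales differ, but uniform treatment avoids an arbitrary
asymmetry.

Evaluation is one-vs-all AUC (rank statistic, ties counted 0.5) averaged
over classes and over stratified outer 5-fold cross-validation. Folds are
stratified with a fixed seed; stratification is a package choice where
the protocol is otherwise silent, and keeps every class present in every
training fold whenever class sizes permit.

## The synthetic generators, and what passing tests show

`makeImage()` produces constant, striped, checkerboard, blob-field and
correlated-noise textures. The correlated-noise generator is a separable
first-order autoregressive field — white noise filtered recursively along
rows then columns — whose lag-1 autocorrelation ρ directly controls the
diagonal concentration of the GLCM; its effect on the Haralick
correlation statistic is monotone and analytically predictable, which is
what makes it a sharp test fixture. The standardized field is mapped to
levels with ±3σ spanning the range, so clipping is rare.
`makeGaussianBumpMatrix()` builds co-occurrence matrices whose level sets
are ellipses known in closed form (including the half-count shift
introduced by rounding), giving exact oracles for the shape and curvature
paths.

These fixtures emulate *spatial correlation structure*, which is the one
property the descriptors measure. They do not emulate illumination
gradients, staining variability, resolution differences within a
dataset, or structured noise of real microscopy — so a passing test
suite demonstrates that the machinery is correct and that the pipeline
separates textures that differ in correlation structure, not that any
particular AUC will be reached on real medical images.

Problem sizes used by the test suite and the acceptance script are
deliberately desk-scale: oracle comparisons on 50 random images up to
32×32 (exact agreement required), 20 Gaussian-bump matrices for ellipse
recovery (5% axes, 5° orientation), and a 100-image 64×64 two-class
benchmark (ρ = 0.2 vs 0.8) for the end-to-end HR/HRsub runs, where the
expected cross-validated AUC is ≥ 0.95.

## Known limitations

- The nine SHAPE evolution features and the curvature radii/bin defaults
  are package-fixed conventions; results are internally consistent but
  not numerically comparable to other implementations of level-curve or
  curvature descriptors.
- Run-length features on the full symmetric matrix carry the 0°/90° and
  45°/135° redundancy noted above; the descriptor keeps all four
  directions for structural compatibility.
- `N = 256` levels is assumed by all window coordinates; deeper inputs
  are rescaled, they are not given larger matrices.
- The LD family stores flattened matrices densely; the memory guard makes
  the limit explicit rather than lifting it.
- Inner-CV model selection on very small folds is noisy; with fewer than
  ~5 samples per class per fold the chosen kernel can vary with the seed
  even though the selection itself is deterministic given the seed.
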