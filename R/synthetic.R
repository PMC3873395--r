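# Synthetic texture generators: labeled image sets with controllable spatial
# statistics, plus analytic Gaussian-bump co-occurrence fixtures whose
# level-set ellipses are known in closed form.

#' Specification of one synthetic texture image
#'
#' @param classId integer class label.
#' @param generator one of `"constant"`, `"stripes"`, `"checkerboard"`,
#'   `"correlated_noise"`, `"blob_field"`.
#' @param size `c(height, width)` in pixels.
#' @param seed RNG seed; the same spec and seed give a bit-identical image.
#' @param nLevels gray levels (default 256).
#' @param ... generator parameters: `level` (constant); `period`,
#'   `orientation` ("h"/"v") (stripes); `cell` (checkerboard); `rho`
#'   (correlated_noise, lag-1 autocorrelation in `[0, 1)`); `density`,
#'   `radius` (blob_field).
#' @return a `TextureSpec` (plain list, class-tagged).
#' @export
textureSpec <- function(classId, generator, size = c(64L, 64L), seed = 1L,
                        nLevels = 256L, ...) {
  spec <- list(classId = as.integer(classId), generator = generator,
               size = as.integer(size), seed = as.integer(seed),
               nLevels = as.integer(nLevels), params = list(...))
  class(spec) <- "TextureSpec"
  spec
}

# First-order separable autoregressive field: white noise filtered
# recursively along rows then columns, giving lag-1 autocorrelation rho in
# both axes (correlation rho^|lag| at larger lags).
ar1Field <- function(h, w, rho) {
  e <- matrix(stats::rnorm(h * w), h, w)
  if (rho > 0) {
    e <- t(apply(e, 1, function(x) as.numeric(stats::filter(x, rho, method = "recursive"))))
    e <- apply(e, 2, function(x) as.numeric(stats::filter(x, rho, method = "recursive")))
  }
  e
}

#' Generate a synthetic texture image
#'
#' Deterministic given the spec (the spec's seed drives all randomness).
#' `correlated_noise` implements a separable first-order autoregressive
#' field whose parameter `rho` controls the diagonal concentration of the
#' co-occurrence matrix: higher `rho` means stronger correlation between
#' neighboring pixels.
#'
#' @param spec a [textureSpec()].
#' @return a [GrayImage-class].
#' @export
makeImage <- function(spec) {
  stopifnot(inherits(spec, "TextureSpec"))
  h <- spec$size[1]; w <- spec$size[2]
  n <- spec$nLevels
  p <- spec$params
  old <- .Random.seed.save()
  on.exit(.Random.seed.restore(old))
  set.seed(spec$seed)
  px <- switch(spec$generator,
    constant = matrix(as.integer(p$level %||% (n %/% 2)), h, w),
    stripes = {
      period <- p$period %||% 4L
      lo <- as.integer(round(0.25 * (n - 1))); hi <- as.integer(round(0.75 * (n - 1)))
      if (identical(p$orientation, "h")) {
        matrix(ifelse((row(matrix(0, h, w)) %/% (period %/% 2L)) %% 2L == 0L, lo, hi), h, w)
      } else {
        matrix(ifelse((col(matrix(0, h, w)) %/% (period %/% 2L)) %% 2L == 0L, lo, hi), h, w)
      }
    },
    checkerboard = {
      cell <- p$cell %||% 2L
      lo <- as.integer(round(0.25 * (n - 1))); hi <- as.integer(round(0.75 * (n - 1)))
      parity <- (row(matrix(0, h, w)) %/% cell + col(matrix(0, h, w)) %/% cell) %% 2L
      matrix(ifelse(parity == 0L, lo, hi), h, w)
    },
    correlated_noise = {
      rho <- p$rho %||% 0.5
      if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)")
      f <- ar1Field(h, w, rho)
      f <- (f - mean(f)) / stats::sd(f)
      q <- round((n - 1) / 2 + f * (n - 1) / 6)   # +-3 sd spans the range
      pmin(pmax(q, 0), n - 1)                     # q first keeps the dim
    },
    blob_field = {
      density <- p$density %||% 0.01
      radius <- p$radius %||% 3
      img <- matrix(as.integer(round(0.25 * (n - 1))), h, w)
      nBlobs <- max(1L, round(density * h * w))
      cr <- sample.int(h, nBlobs, replace = TRUE)
      cc <- sample.int(w, nBlobs, replace = TRUE)
      lev <- sample(seq(round(0.5 * (n - 1)), n - 1), nBlobs, replace = TRUE)
      rr <- row(img); cl <- col(img)
      for (b in seq_len(nBlobs)) {
        inside <- (rr - cr[b])^2 + (cl - cc[b])^2 <= radius^2
        img[inside] <- as.integer(lev[b])
      }
      img
    },
    stop("unknown generator: ", spec$generator))
  storage.mode(px) <- "integer"
  new("GrayImage", pixels = px, nLevels = n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.Random.seed.save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed.restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a balanced labeled dataset of synthetic textures
#'
#' Every image gets its own seed derived from the dataset seed, so
#' regeneration is reproducible image-by-image.
#'
#' @param nPerClass images per class (a warning is issued below 5: CV folds
#'   would be tiny).
#' @param classSpecs named list: one [textureSpec()] template per class
#'   (its `classId` and `seed` are overridden per image).
#' @param seed dataset seed.
#' @return list with `images` (list of [GrayImage-class]), `labels`
#'   (integer vector) and `manifest` (data.frame with id, label, seed,
#'   generator).
#' @export
makeDataset <- function(nPerClass, classSpecs, seed = 1L) {
  stopifnot(length(classSpecs) >= 2L)
  if (nPerClass < 5L) warning("fewer than 5 images per class: CV folds will be tiny")
  images <- list(); labels <- integer(0); rows <- list()
  k <- 0L
  for (ci in seq_along(classSpecs)) {
    tpl <- classSpecs[[ci]]
    for (j in seq_len(nPerClass)) {
      k <- k + 1L
      sp <- tpl
      sp$classId <- ci
      sp$seed <- as.integer((seed %% 214747L) * 10000L + k)
      images[[k]] <- makeImage(sp)
      labels[k] <- ci
      rows[[k]] <- data.frame(id = sprintf("img%04d", k), label = ci,
                              seed = sp$seed, generator = sp$generator,
                              stringsAsFactors = FALSE)
    }
  }
  list(images = images, labels = labels, manifest = do.call(rbind, rows))
}

#' Write a dataset to disk as PNG images plus a CSV manifest
#'
#' @param ds result of [makeDataset()].
#' @param dir output directory (created if missing).
#' @return the manifest path.
#' @export
writeDataset <- function(ds, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(length(ds$images))
  for (k in seq_along(ds$images)) {
    paths[k] <- file.path(dir, paste0(ds$manifest$id[k], ".png"))
    img <- ds$images[[k]]
    EBImage::writeImage(t(img@pixels / (img@nLevels - 1)), paths[k])
  }
  man <- ds$manifest
  man$path <- paths
  manPath <- file.path(dir, "manifest.csv")
  utils::write.csv(man, manPath, row.names = FALSE)
  manPath
}

#' Analytic Gaussian-bump co-occurrence fixture
#'
#' Builds `counts[i, j] = round(amplitude * exp(-0.5 * delta' Sigma^-1
#' delta))`, whose level sets `counts > h` are ellipses known in closed
#' form; the returned object carries an `levelEllipse(h)` attribute giving
#' the analytic semi-axes, axis ratio and orientation at height `h`
#' (accounting for the rounding of counts).
#'
#' @param center `c(row, col)` of the bump (1-based bin coordinates).
#' @param covariance 2x2 positive-definite matrix (row/col coordinates).
#' @param amplitude peak height.
#' @param nLevels matrix size (default 256).
#' @return a [CooccurrenceMatrix-class] with attribute `levelEllipse`.
#' @export
makeGaussianBumpMatrix <- function(center, covariance, amplitude,
                                   nLevels = 256L) {
  ev <- eigen(covariance, symmetric = TRUE)
  if (any(ev$values <= 0)) stop("covariance must be positive definite")
  Sinv <- solve(covariance)
  i <- seq_len(nLevels)
  dr <- matrix(i - center[1], nLevels, nLevels)
  dc <- matrix(i - center[2], nLevels, nLevels, byrow = TRUE)
  q <- Sinv[1, 1] * dr^2 + 2 * Sinv[1, 2] * dr * dc + Sinv[2, 2] * dc^2
  ct <- round(amplitude * exp(-0.5 * q))
  storage.mode(ct) <- "integer"
  m <- new("CooccurrenceMatrix", counts = ct, d = 1L, theta = 0,
           sourceDims = c(nLevels, nLevels), full = TRUE)
  # rounded counts exceed h iff amplitude * exp(-q/2) >= h + 0.5
  levelEllipse <- function(h) {
    if (amplitude < h + 0.5) return(NULL)
    c2 <- 2 * log(amplitude / (h + 0.5))
    semi <- sqrt(ev$values * c2)
    vmaj <- ev$vectors[, 1]
    ang <- atan2(vmaj[2], vmaj[1])   # angle from row axis, in (row, col)
    if (ang >= pi / 2) ang <- ang - pi
    if (ang < -pi / 2) ang <- ang + pi
    list(semiMajor = semi[1], semiMinor = semi[2],
         axisRatio = semi[1] / semi[2], orientation = ang)
  }
  attr(m, "levelEllipse") <- levelEllipse
  m
}
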