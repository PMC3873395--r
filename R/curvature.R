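# Curvature (CR) descriptor: area-ratio curvature measured with circular
# masks centered on the contour of the main level-curve blob, quantized into
# equal-width histograms.

#' Contour points of a level-slice main blob
#'
#' Boundary pixels are blob pixels with at least one 4-neighbor outside the
#' blob; pixels on the matrix border count as boundary (the outside is
#' background).
#'
#' @param slice one element of [levelSlices()] output.
#' @return 2-column matrix of (row, col) contour coordinates (0 rows when
#'   the blob is empty).
#' @export
contourPoints <- function(slice) {
  blob <- slice$mainBlob
  if (nrow(blob) == 0L) return(blob)
  dm <- dim(slice$mask)
  inBlob <- matrix(FALSE, dm[1], dm[2])
  inBlob[blob] <- TRUE
  # pad with background so border pixels see an outside neighbor
  pad <- matrix(FALSE, dm[1] + 2L, dm[2] + 2L)
  pad[2:(dm[1] + 1L), 2:(dm[2] + 1L)] <- inBlob
  core <- pad[2:(dm[1] + 1L), 2:(dm[2] + 1L)]
  up    <- pad[1:dm[1], 2:(dm[2] + 1L)]
  down  <- pad[3:(dm[1] + 2L), 2:(dm[2] + 1L)]
  left  <- pad[2:(dm[1] + 1L), 1:dm[2]]
  right <- pad[2:(dm[1] + 1L), 3:(dm[2] + 2L)]
  boundary <- core & !(up & down & left & right)
  idx <- which(boundary)
  cbind(row = (idx - 1L) %% dm[1] + 1L, col = (idx - 1L) %/% dm[1] + 1L)
}

# Binary disc mask of radius r (pixels with center distance <= r).
discKernel <- function(r) {
  z <- -r:r
  k <- outer(z^2, z^2, "+") <= r^2
  storage.mode(k) <- "numeric"
  k
}

#' Area-ratio curvature at one contour point
#'
#' Fraction of the circular mask of radius `r` centered at `p` that is
#' covered by the main blob: about 0.5 on a straight edge, below 0.5 on
#' convex contours, above 0.5 on concave ones. Contour pixels straddle the
#' true (sub-pixel) boundary, so they contribute with weight 1/2; this
#' midpoint correction removes the O(1/r) bias that full-weight counting
#' shows on straight edges at small radii.
#'
#' @param slice one element of [levelSlices()] output.
#' @param p `c(row, col)` of a contour point.
#' @param r mask radius in pixels (>= 1).
#' @return numeric in `[0, 1]`.
#' @export
curvatureMeasure <- function(slice, p, r) {
  if (r < 1) stop("radius must be >= 1")
  blob <- slice$mainBlob
  if (nrow(blob) == 0L) return(0)
  cps <- contourPoints(slice)
  d2b <- (blob[, 1] - p[1])^2 + (blob[, 2] - p[2])^2
  d2c <- (cps[, 1] - p[1])^2 + (cps[, 2] - p[2])^2
  (sum(d2b <= r^2) - 0.5 * sum(d2c <= r^2)) / sum(discKernel(r))
}

# Curvature values for all contour points at once (convolution of the blob
# and contour masks with the disc kernel, sampled at the contour).
curvatureAtContour <- function(slice, r) {
  cps <- contourPoints(slice)
  if (nrow(cps) == 0L) return(numeric(0))
  dm <- dim(slice$mask)
  inBlob <- matrix(0, dm[1], dm[2])
  inBlob[slice$mainBlob] <- 1
  onContour <- matrix(0, dm[1], dm[2])
  onContour[cps] <- 1
  k <- discKernel(r)
  conv <- EBImage::filter2(inBlob, k, boundary = 0) -
    0.5 * EBImage::filter2(onContour, k, boundary = 0)
  pmin(pmax(conv[cps] / sum(k), 0), 1)
}

#' Curvature histogram descriptor of one co-occurrence matrix
#'
#' The matrix is sliced at heights 1, 4, ..., 13 (default
#' `seq(1, 15, by = 3)`); for each level and each mask radius, the
#' area-ratio curvature is evaluated at every contour point of the main blob
#' and quantized into `nBins` equal-width bins on `[0, 1]`. Each per-radius
#' histogram is normalized to sum 1 (all-zero when the level is empty); the
#' concatenation over levels and radii has length
#' `length(heights) * length(radii) * nBins`.
#'
#' @param m a [CooccurrenceMatrix-class].
#' @param radii mask radii (default `c(3, 5, 7)`).
#' @param nBins histogram bins (default 8).
#' @param heights slice heights (default `seq(1, 15, by = 3)`).
#' @return named numeric vector with an `empty` attribute (TRUE when every
#'   level is empty).
#' @export
cuMatrixFeatures <- function(m, radii = c(3, 5, 7), nBins = 8L,
                             heights = seq(1, 15, by = 3)) {
  stopifnot(is(m, "CooccurrenceMatrix"))
  slices <- levelSlices(m, heights)
  breaks <- seq(0, 1, length.out = nBins + 1L)
  blocks <- list()
  anyPoint <- FALSE
  for (s in slices) {
    for (r in radii) {
      cv <- curvatureAtContour(s, r)
      if (length(cv) > 0L) {
        anyPoint <- TRUE
        cv[cv > 1] <- 1; cv[cv < 0] <- 0
        hh <- graphics::hist(cv, breaks = breaks, plot = FALSE)$counts
        hh <- hh / sum(hh)
      } else {
        hh <- numeric(nBins)
      }
      blocks[[sprintf("h%g_r%g", s$height, r)]] <-
        stats::setNames(hh, sprintf("h%g_r%g_b%d", s$height, r, seq_len(nBins)))
    }
  }
  out <- unlist(unname(blocks))
  attr(out, "empty") <- !anyPoint
  out
}

#' Curvature descriptor over a co-occurrence matrix set
#'
#' Concatenates [cuMatrixFeatures()] over every (d, theta) matrix of the
#' set (optionally cropped to a window); default length
#' 5 levels x 3 radii x 8 bins x 8 matrices = 960.
#'
#' @param s a [GlcmSet-class].
#' @param window optional [MatrixWindow-class].
#' @param radii,nBins,heights passed to [cuMatrixFeatures()].
#' @return named numeric vector, names `cu_d{d}_t{theta}_h{h}_r{r}_b{b}`.
#' @export
cuDescriptor <- function(s, window = NULL, radii = c(3, 5, 7), nBins = 8L,
                         heights = seq(1, 15, by = 3)) {
  stopifnot(is(s, "GlcmSet"))
  out <- lapply(names(s@matrices), function(nm) {
    m <- s@matrices[[nm]]
    if (!is.null(window)) m <- cropWindow(m, window)
    v <- cuMatrixFeatures(m, radii, nBins, heights)
    stats::setNames(as.numeric(v), sprintf("cu_%s_%s", nm, names(v)))
  })
  unlist(out)
}
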