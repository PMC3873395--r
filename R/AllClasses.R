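#' @import methods
NULL

#' Quantized grayscale image
#'
#' A 2D raster of integer gray levels in `[0, nLevels - 1]`, the common input
#' of every descriptor path in the package. Images read from disk or produced
#' by [toGray()] are always quantized to `nLevels` (256 by default) so the
#' co-occurrence matrix is a well-defined histogram over discrete levels.
#'
#' @slot pixels integer matrix of gray levels (rows = image rows).
#' @slot nLevels number of gray levels (bins of the co-occurrence matrix).
#'
#' @aliases GrayImage-class
#' @exportClass GrayImage
setClass("GrayImage",
  representation(pixels = "matrix", nLevels = "integer"),
  validity = function(object) {
    p <- object@pixels
    if (!is.numeric(p)) return("pixels must be numeric")
    if (nrow(p) < 2L || ncol(p) < 2L)
      return("image must be at least 2x2 (a co-occurrence matrix needs at least one pixel pair)")
    if (anyNA(p)) return("pixels contain NA")
    if (any(p != round(p))) return("pixels must be integer-valued")
    if (min(p) < 0 || max(p) > object@nLevels - 1L)
      return(sprintf("pixel values must lie in [0, %d]", object@nLevels - 1L))
    if (object@nLevels < 2L) return("nLevels must be >= 2")
    TRUE
  }
)

#' Gray-level co-occurrence matrix for one (d, theta)
#'
#' Histogram of gray-level transitions between pixel pairs at displacement
#' distance `d` and orientation `theta` (degrees; 0 = horizontal, 45 =
#' up-right diagonal, 90 = vertical, 135 = up-left diagonal). Accumulation is
#' symmetric: each pixel pair is counted in both orders, so the counts of a
#' full (uncropped) matrix form a symmetric matrix summing to twice the
#' number of valid pairs.
#'
#' @slot counts non-negative integer matrix, `nLevels x nLevels` for a full
#'   matrix (possibly rectangular after [cropWindow()]).
#' @slot d displacement distance in pixels.
#' @slot theta orientation in degrees, one of 0, 45, 90, 135.
#' @slot sourceDims dimensions of the originating image.
#' @slot full TRUE for a whole-matrix object, FALSE after cropping.
#'
#' @aliases CooccurrenceMatrix-class
#' @exportClass CooccurrenceMatrix
setClass("CooccurrenceMatrix",
  representation(counts = "matrix", d = "integer", theta = "numeric",
                 sourceDims = "integer", full = "logical"),
  validity = function(object) {
    ct <- object@counts
    if (anyNA(ct) || any(ct < 0)) return("counts must be non-negative")
    if (any(ct != round(ct))) return("counts must be integers")
    if (!object@theta %in% c(0, 45, 90, 135))
      return("theta must be one of 0, 45, 90, 135")
    if (object@d < 1L) return("d must be >= 1")
    TRUE
  }
)

#' The set of co-occurrence matrices of one image
#'
#' One [CooccurrenceMatrix-class] per combination of distance and
#' orientation; the default grid d in \{1, 3\} times theta in \{0, 45, 90,
#' 135\} gives eight matrices. Descriptors are concatenated over the set in
#' a fixed d-major, theta-minor order.
#'
#' @slot matrices named list of [CooccurrenceMatrix-class] objects, names
#'   `"d{d}_t{theta}"`.
#' @slot distances the distance grid.
#' @slot thetas the orientation grid (degrees).
#' @slot nLevels shared number of gray levels.
#'
#' @aliases GlcmSet-class
#' @exportClass GlcmSet
setClass("GlcmSet",
  representation(matrices = "list", distances = "integer",
                 thetas = "numeric", nLevels = "integer"),
  validity = function(object) {
    nexp <- length(object@distances) * length(object@thetas)
    if (length(object@matrices) != nexp)
      return(sprintf("expected %d matrices, got %d", nexp, length(object@matrices)))
    if (!all(vapply(object@matrices, is, logical(1), "CooccurrenceMatrix")))
      return("all elements must be CooccurrenceMatrix objects")
    TRUE
  }
)

#' Rectangular window of a co-occurrence matrix
#'
#' Inclusive corner coordinates in the 0-based bin indexing of the matrix,
#' so `(0,0)` to `(127,127)` spans 128 bins in each direction.
#'
#' @slot origin integer c(row, col), 0-based inclusive.
#' @slot corner integer c(row, col), 0-based inclusive.
#' @slot label window identifier (e.g. "whole", "q1", "w7").
#'
#' @aliases MatrixWindow-class
#' @exportClass MatrixWindow
setClass("MatrixWindow",
  representation(origin = "integer", corner = "integer", label = "character"),
  validity = function(object) {
    if (any(object@origin < 0L) || any(object@corner < object@origin))
      return("window corners must satisfy 0 <= origin <= corner")
    TRUE
  }
)

#' Run-length matrix
#'
#' `p[i, j]` counts the maximal runs of (0-based) gray level `i - 1` and
#' length `j` along scan lines in direction `thetaGL`. Every pixel of the
#' analyzed image belongs to exactly one run, so
#' `sum(j * p[, j]) == nPixels`.
#'
#' @slot p non-negative integer matrix (levels x max run length).
#' @slot thetaGL run direction in degrees (0, 45, 90, 135).
#' @slot nRuns total number of runs.
#' @slot nPixels total number of pixels in the analyzed image.
#'
#' @aliases RunLengthMatrix-class
#' @exportClass RunLengthMatrix
setClass("RunLengthMatrix",
  representation(p = "matrix", thetaGL = "numeric", nRuns = "integer",
                 nPixels = "integer"),
  validity = function(object) {
    if (any(object@p < 0)) return("run counts must be non-negative")
    if (sum(object@p) != object@nRuns) return("nRuns must equal sum(p)")
    jj <- seq_len(ncol(object@p))
    if (sum(object@p %*% jj) != object@nPixels)
      return("sum over runs of j * p(i,j) must equal nPixels")
    TRUE
  }
)

#' PCA subspace model for direct co-occurrence-matrix descriptors
#'
#' Fitted on training-fold matrices only; holds the mean of the flattened
#' matrices and the smallest orthonormal basis whose cumulative explained
#' variance reaches the retention threshold (0.99 by default).
#'
#' @slot center mean of the flattened training matrices.
#' @slot basis columns are orthonormal principal directions.
#' @slot varianceExplained per-component explained-variance fractions.
#' @slot retainedVariance cumulative fraction retained by the basis.
#' @slot nComponents number of components kept.
#' @slot normalize whether matrices are count-normalized before projection.
#' @slot key the (d, theta, window, scale) slot the model serves.
#'
#' @aliases SubspaceModel-class
#' @exportClass SubspaceModel
setClass("SubspaceModel",
  representation(center = "numeric", basis = "matrix",
                 varianceExplained = "numeric", retainedVariance = "numeric",
                 nComponents = "integer", normalize = "logical",
                 key = "character"),
  validity = function(object) {
    if (ncol(object@basis) != object@nComponents)
      return("basis must have nComponents columns")
    g <- crossprod(object@basis)
    if (max(abs(g - diag(ncol(g)))) > 1e-8)
      return("basis columns must be orthonormal")
    if (is.unsorted(rev(object@varianceExplained), strictly = FALSE))
      return("explained-variance fractions must be non-increasing")
    TRUE
  }
)

#' Per-sample, per-class classifier scores
#'
#' The unit of weighted-sum fusion: decision scores of one SVM (one
#' descriptor/window/scale panel) for every sample and class. After
#' normalization every column has mean 0 and population standard deviation 1
#' (constant columns map to 0).
#'
#' @slot scores numeric matrix, samples x classes.
#' @slot source identifier of the producing panel.
#' @slot normalized whether columnwise z-scoring has been applied.
#'
#' @aliases ScorePanel-class
#' @exportClass ScorePanel
setClass("ScorePanel",
  representation(scores = "matrix", source = "character", normalized = "logical"),
  validity = function(object) {
    if (anyNA(object@scores)) return("scores contain NA")
    if (object@normalized && nrow(object@scores) > 1) {
      mu <- colMeans(object@scores)
      sdev <- sqrt(colMeans(sweep(object@scores, 2, mu)^2))
      ok <- abs(mu) < 1e-8 & (abs(sdev - 1) < 1e-6 | sdev < 1e-8)
      if (!all(ok)) return("normalized panel must have columns with mean 0 and sd 1 (or constant 0)")
    }
    TRUE
  }
)

setMethod("show", "GrayImage", function(object) {
  cat(sprintf("GrayImage: %d x %d, %d gray levels, range [%d, %d]\n",
              nrow(object@pixels), ncol(object@pixels), object@nLevels,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "CooccurrenceMatrix", function(object) {
  cat(sprintf("CooccurrenceMatrix: %d x %d bins, d = %d, theta = %g deg, total = %d%s\n",
              nrow(object@counts), ncol(object@counts), object@d, object@theta,
              sum(object@counts), if (object@full) "" else " (cropped)"))
})

setMethod("show", "GlcmSet", function(object) {
  cat(sprintf("GlcmSet: %d matrices (d = {%s}, theta = {%s}), %d gray levels\n",
              length(object@matrices),
              paste(object@distances, collapse = ","),
              paste(object@thetas, collapse = ","), object@nLevels))
})

setMethod("show", "RunLengthMatrix", function(object) {
  cat(sprintf("RunLengthMatrix: %d levels x max length %d, theta_GL = %g deg, %d runs over %d pixels\n",
              nrow(object@p), ncol(object@p), object@thetaGL, object@nRuns,
              object@nPixels))
})

setMethod("show", "SubspaceModel", function(object) {
  cat(sprintf("SubspaceModel [%s]: %d components, %.4f variance retained\n",
              object@key, object@nComponents, object@retainedVariance))
})

setMethod("show", "ScorePanel", function(object) {
  cat(sprintf("ScorePanel [%s]: %d samples x %d classes%s\n", object@source,
              nrow(object@scores), ncol(object@scores),
              if (object@normalized) ", normalized" else ""))
})

# ---- accessors ------------------------------------------------------------

#' Accessors for cooctex containers
#'
#' @param x a cooctex S4 object.
#' @return `pixels()` the integer pixel matrix; `nLevels()` the number of
#'   gray levels; `counts()` the raw co-occurrence counts; `glcmMatrices()`
#'   the named list of matrices in a [GlcmSet-class]; `panelScores()` the
#'   score matrix of a [ScorePanel-class].
#' @name accessors
NULL

#' @rdname accessors
#' @export
pixels <- function(x) {
  stopifnot(is(x, "GrayImage"))
  x@pixels
}

#' @rdname accessors
#' @export
nLevels <- function(x) {
  if (is(x, "GrayImage")) return(x@nLevels)
  if (is(x, "GlcmSet")) return(x@nLevels)
  stop("no nLevels for this object")
}

#' @rdname accessors
#' @export
counts <- function(x) {
  stopifnot(is(x, "CooccurrenceMatrix"))
  x@counts
}

#' @rdname accessors
#' @export
glcmMatrices <- function(x) {
  stopifnot(is(x, "GlcmSet"))
  x@matrices
}

#' @rdname accessors
#' @export
panelScores <- function(x) {
  stopifnot(is(x, "ScorePanel"))
  x@scores
}
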