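#' Names of the 13 Haralick statistics, in canonical order
#' @export
haralickNames <- c(
  "energy", "correlation", "inertia", "entropy", "idm",
  "sum_average", "sum_variance", "sum_entropy",
  "diff_average", "diff_variance", "diff_entropy",
  "imc1", "imc2"
)

#' The 13 Haralick statistics of one co-occurrence matrix
#'
#' The matrix is normalized to a joint probability table
#' `p(i, j) = counts / sum(counts)` and the classical statistics are
#' evaluated from `p`, its marginals and the sum (`i + j`) and difference
#' (`|i - j|`) distributions. Logarithms are base 2 with the
#' `0 * log 0 := 0` convention. `sum_variance` is the variance of the sum
#' distribution about its own mean (the sum average), and `diff_variance`
#' the variance of the difference distribution about its mean; both are
#' constant, documented choices among the variants circulating in the
#' literature.
#'
#' For a degenerate matrix whose marginal variance is zero (all mass at a
#' single level) `correlation` and `imc1` are returned as 0 with a warning,
#' which keeps subwindow pipelines total.
#'
#' @param m a [CooccurrenceMatrix-class] (raw counts; any rectangular crop).
#' @return named numeric vector of length 13 (see [haralickNames]).
#' @examples
#' img <- grayImage(matrix(sample(0:15, 64, TRUE), 8, 8), nLevels = 16L)
#' haralick13(computeGLCM(img, 1, 0))
#' @export
haralick13 <- function(m) {
  stopifnot(is(m, "CooccurrenceMatrix"))
  ct <- m@counts
  total <- sum(ct)
  if (total <= 0) stop("empty matrix: all counts are zero")
  p <- ct / total
  nr <- nrow(p); nc <- ncol(p)
  i <- seq_len(nr) - 1L
  j <- seq_len(nc) - 1L
  px <- rowSums(p)
  py <- colSums(p)

  energy <- sum(p^2)
  entropy <- -sum(xlog2x(p))

  mux <- sum(i * px); muy <- sum(j * py)
  sdx <- sqrt(sum((i - mux)^2 * px))
  sdy <- sqrt(sum((j - muy)^2 * py))
  ij <- outer(i, j)
  if (sdx * sdy < 1e-300) {
    warning("degenerate matrix (zero marginal variance): correlation set to 0")
    correlation <- 0
  } else {
    correlation <- (sum(ij * p) - mux * muy) / (sdx * sdy)
  }

  dmat <- outer(i, j, "-")
  inertia <- sum(dmat^2 * p)
  idm <- sum(p / (1 + dmat^2))

  # sum and difference distributions
  smat <- outer(i, j, "+")
  psum <- as.vector(rowsum(as.vector(p), as.vector(smat)))
  ks <- sort(unique(as.vector(smat)))
  sumAverage <- sum(ks * psum)
  sumVariance <- sum((ks - sumAverage)^2 * psum)
  sumEntropy <- -sum(xlog2x(psum))

  amat <- abs(dmat)
  pdiff <- as.vector(rowsum(as.vector(p), as.vector(amat)))
  kd <- sort(unique(as.vector(amat)))
  diffAverage <- sum(kd * pdiff)
  diffVariance <- sum((kd - diffAverage)^2 * pdiff)
  diffEntropy <- -sum(xlog2x(pdiff))

  # information measures of correlation
  hx <- -sum(xlog2x(px))
  hy <- -sum(xlog2x(py))
  pxy <- outer(px, py)
  pos <- p > 0
  hxy1 <- -sum(p[pos] * log2(pxy[pos]))
  hxy2 <- -sum(xlog2x(pxy))
  if (max(hx, hy) < 1e-300) {
    warning("degenerate matrix (zero marginal entropy): imc1 set to 0")
    imc1 <- 0
  } else {
    imc1 <- (entropy - hxy1) / max(hx, hy)
  }
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))

  c(energy = energy, correlation = correlation, inertia = inertia,
    entropy = entropy, idm = idm,
    sum_average = sumAverage, sum_variance = sumVariance,
    sum_entropy = sumEntropy,
    diff_average = diffAverage, diff_variance = diffVariance,
    diff_entropy = diffEntropy, imc1 = imc1, imc2 = imc2)
}

#' Haralick descriptor over a co-occurrence matrix set
#'
#' Concatenates the 13 statistics over every (d, theta) matrix of the set in
#' d-major, theta-minor order; with the default grid this gives a
#' 104-dimensional descriptor. If a window is given, each matrix is cropped
#' first. A window with zero total count contributes a documented sentinel
#' of 13 zeros (with a warning) instead of aborting the pipeline.
#'
#' @param s a [GlcmSet-class].
#' @param window optional [MatrixWindow-class].
#' @return named numeric vector, names `har_d{d}_t{theta}_{stat}`.
#' @export
harDescriptor <- function(s, window = NULL) {
  stopifnot(is(s, "GlcmSet"))
  out <- lapply(names(s@matrices), function(nm) {
    m <- s@matrices[[nm]]
    if (!is.null(window)) m <- cropWindow(m, window)
    v <- if (sum(m@counts) == 0) {
      warning(sprintf("window has zero total count for %s: features set to 0", nm))
      stats::setNames(numeric(13), haralickNames)
    } else haralick13(m)
    stats::setNames(v, sprintf("har_%s_%s", nm, haralickNames))
  })
  unlist(out)
}
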