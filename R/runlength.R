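#' Names of the 11 run-length indicators
#' @export
rlNames <- c("SRE", "LRE", "GLN", "RLN", "RP",
             "LGRE", "HGRE", "SRLGE", "SRHGE", "LRLGE", "LRHGE")

#' Quantize a co-occurrence matrix to a run-able gray image
#'
#' Run-length analysis of the co-occurrence matrix requires its raw counts
#' to be mapped onto a small number of discrete levels. Counts are
#' heavy-tailed, so a logarithmic compression is used:
#' `level = floor(nLevels * log(1 + c) / log(1 + max(c)))`, clipped to
#' `[0, nLevels - 1]`. An all-zero matrix maps to an all-zero image.
#'
#' @param m a [CooccurrenceMatrix-class].
#' @param nLevels number of quantized levels (default 16).
#' @return a [GrayImage-class] the size of the (possibly cropped) matrix.
#' @export
quantizeGLCM <- function(m, nLevels = 16L) {
  stopifnot(is(m, "CooccurrenceMatrix"))
  nLevels <- as.integer(nLevels)
  if (nLevels < 2L) stop("nLevels must be >= 2")
  ct <- m@counts
  mx <- max(ct)
  if (mx == 0) {
    q <- matrix(0L, nrow(ct), ncol(ct))
  } else {
    q <- floor(nLevels * log1p(ct) / log1p(mx))
    q[q > nLevels - 1L] <- nLevels - 1L
    storage.mode(q) <- "integer"
  }
  new("GrayImage", pixels = q, nLevels = nLevels)
}

# Decompose the image into ordered scan lines for a run direction.
scanLines <- function(px, thetaGL) {
  h <- nrow(px); w <- ncol(px)
  switch(as.character(thetaGL),
    "0"   = lapply(seq_len(h), function(r) px[r, ]),
    "90"  = lapply(seq_len(w), function(c) px[, c]),
    "45"  = {  # up-right anti-diagonals: constant row + col
      rc <- row(px) + col(px)
      o <- order(rc, -row(px))
      split(px[o], rc[o])
    },
    "135" = {  # down-right diagonals: constant row - col
      rc <- row(px) - col(px)
      o <- order(rc, row(px))
      split(px[o], rc[o])
    },
    stop("thetaGL must be one of 0, 45, 90, 135"))
}

#' Gray-level run-length matrix
#'
#' A run is a maximal set of consecutive pixels with the same value along a
#' scan line; `p[i, j]` counts runs of (0-based) level `i - 1` and length
#' `j` in direction `thetaGL`. Diagonal directions enumerate every diagonal
#' of the image, including the length-1 corners.
#'
#' @param img a [GrayImage-class] (here, typically a quantized
#'   co-occurrence matrix from [quantizeGLCM()]).
#' @param thetaGL run direction in degrees (0, 45, 90, 135).
#' @return a [RunLengthMatrix-class].
#' @examples
#' img <- grayImage(matrix(0L, 4, 6), nLevels = 16L)
#' runLengthMatrix(img, 0)  # 4 runs of length 6
#' @export
runLengthMatrix <- function(img, thetaGL) {
  stopifnot(is(img, "GrayImage"))
  px <- img@pixels
  lines <- scanLines(px, thetaGL)
  maxLen <- max(nrow(px), ncol(px))
  rl <- lapply(lines, function(ln) rle(as.integer(ln)))
  vals <- unlist(lapply(rl, `[[`, "values"), use.names = FALSE)
  lens <- unlist(lapply(rl, `[[`, "lengths"), use.names = FALSE)
  tab <- tabulate(vals * maxLen + lens, nbins = img@nLevels * maxLen)
  p <- matrix(tab, img@nLevels, maxLen, byrow = TRUE)
  storage.mode(p) <- "integer"
  new("RunLengthMatrix", p = p, thetaGL = as.numeric(thetaGL),
      nRuns = sum(p), nPixels = length(px))
}

#' The 11 run-length indicators
#'
#' Classical run-length statistics: short/long run emphasis, gray-level and
#' run-length nonuniformity, run percentage, and the low/high gray level
#' emphasis family. Gray levels are 0-based, so the level weight in the
#' LGRE/HGRE family uses `i + 1` to avoid division by zero at level 0.
#'
#' @param P a [RunLengthMatrix-class] with at least one run.
#' @return named numeric vector of length 11 (see [rlNames]).
#' @export
rlIndicators <- function(P) {
  stopifnot(is(P, "RunLengthMatrix"))
  p <- P@p
  nr <- P@nRuns
  if (nr <= 0) stop("empty run matrix")
  np <- P@nPixels
  jw <- seq_len(ncol(p))          # run lengths
  iw <- seq_len(nrow(p))          # gray level + 1
  j2 <- matrix(jw^2, nrow(p), ncol(p), byrow = TRUE)
  i2 <- matrix(iw^2, nrow(p), ncol(p))
  c(SRE  = sum(p / j2) / nr,
    LRE  = sum(p * j2) / nr,
    GLN  = sum(rowSums(p)^2) / nr,
    RLN  = sum(colSums(p)^2) / nr,
    RP   = nr / np,
    LGRE = sum(p / i2) / nr,
    HGRE = sum(p * i2) / nr,
    SRLGE = sum(p / (i2 * j2)) / nr,
    SRHGE = sum(p * i2 / j2) / nr,
    LRLGE = sum(p * j2 / i2) / nr,
    LRHGE = sum(p * i2 * j2) / nr)
}

#' Run-length descriptor of a co-occurrence matrix set
#'
#' For every (d, theta) matrix of the set (optionally cropped to a window),
#' the matrix is quantized with [quantizeGLCM()] and the 11 indicators are
#' computed for each run direction theta_GL in \{0, 45, 90, 135\}. With the
#' default grid the concatenation has length 11 x 4 x 4 x 2 = 352.
#'
#' @param s a [GlcmSet-class].
#' @param window optional [MatrixWindow-class].
#' @param rlLevels quantization levels for [quantizeGLCM()] (default 16).
#' @param thetasGL run directions (default `c(0, 45, 90, 135)`).
#' @return named numeric vector, names `gl_d{d}_t{theta}_r{thetaGL}_{stat}`.
#' @export
glDescriptor <- function(s, window = NULL, rlLevels = 16L,
                         thetasGL = c(0, 45, 90, 135)) {
  stopifnot(is(s, "GlcmSet"))
  out <- lapply(names(s@matrices), function(nm) {
    m <- s@matrices[[nm]]
    if (!is.null(window)) m <- cropWindow(m, window)
    q <- quantizeGLCM(m, rlLevels)
    blocks <- lapply(thetasGL, function(tg) {
      v <- rlIndicators(runLengthMatrix(q, tg))
      stats::setNames(v, sprintf("gl_%s_r%g_%s", nm, tg, rlNames))
    })
    unlist(blocks)
  })
  unlist(out)
}
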