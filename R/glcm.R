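# Displacement (row, col) for each orientation; rows grow downward, so the
# three non-horizontal directions point upward as drawn on screen.
thetaOffset <- function(d, theta) {
  switch(as.character(theta),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop("theta must be one of 0, 45, 90, 135"))
}

#' Compute the gray-level co-occurrence matrix
#'
#' Counts gray-level transitions between pixel pairs separated by the
#' displacement implied by distance `d` and orientation `theta`. Each valid
#' pair `(p, q)` increments both `counts[v(p), v(q)]` and
#' `counts[v(q), v(p)]` (symmetric convention), so the total count is twice
#' the number of valid pairs.
#'
#' @param img a [GrayImage-class].
#' @param d displacement distance in pixels (>= 1).
#' @param theta orientation in degrees: 0 (horizontal), 45 (up-right),
#'   90 (vertical), 135 (up-left).
#' @return a [CooccurrenceMatrix-class] of dimension `nLevels x nLevels`.
#' @examples
#' img <- grayImage(matrix(c(0L, 0L, 1L, 1L), 2, 2), nLevels = 4L)
#' counts(computeGLCM(img, 1, 0))
#' @export
computeGLCM <- function(img, d, theta) {
  stopifnot(is(img, "GrayImage"))
  d <- as.integer(d)
  if (d < 1L) stop("d must be >= 1")
  px <- img@pixels
  h <- nrow(px); w <- ncol(px)
  off <- thetaOffset(d, theta)
  rows <- seq_len(h)
  cols <- seq_len(w)
  rows <- rows[rows + off[1] >= 1L & rows + off[1] <= h]
  cols <- cols[cols + off[2] >= 1L & cols + off[2] <= w]
  if (length(rows) == 0L || length(cols) == 0L)
    stop(sprintf("no valid pixel pairs at d = %d, theta = %g for a %d x %d image",
                 d, theta, h, w))
  n <- img@nLevels
  a <- px[rows, cols, drop = FALSE]
  b <- px[rows + off[1], cols + off[2], drop = FALSE]
  tab <- tabulate(as.integer(a) * n + as.integer(b) + 1L, nbins = n * n)
  cts <- matrix(tab, n, n, byrow = TRUE)   # row = first pixel's level
  cts <- cts + t(cts)
  storage.mode(cts) <- "integer"
  new("CooccurrenceMatrix", counts = cts, d = d, theta = as.numeric(theta),
      sourceDims = c(h, w), full = TRUE)
}

#' Compute the full set of co-occurrence matrices
#'
#' One matrix per combination of `distances` and `thetas`; the default grid
#' (d in \{1, 3\}, theta in \{0, 45, 90, 135\}) yields eight matrices, the
#' basis of every descriptor in the package.
#'
#' @param img a [GrayImage-class].
#' @param distances integer distances (default `c(1, 3)`).
#' @param thetas orientations in degrees (default `c(0, 45, 90, 135)`).
#' @return a [GlcmSet-class]; matrices are named `"d{d}_t{theta}"` in
#'   d-major, theta-minor order.
#' @export
glcmSet <- function(img, distances = c(1L, 3L), thetas = c(0, 45, 90, 135)) {
  stopifnot(is(img, "GrayImage"))
  distances <- as.integer(distances)
  mats <- list()
  for (d in distances) for (th in thetas) {
    mats[[sprintf("d%d_t%g", d, th)]] <- computeGLCM(img, d, th)
  }
  new("GlcmSet", matrices = mats, distances = distances,
      thetas = as.numeric(thetas), nLevels = img@nLevels)
}

#' Construct a matrix window
#'
#' @param origin,corner integer `c(row, col)` in 0-based inclusive bin
#'   coordinates of the co-occurrence matrix.
#' @param label window identifier.
#' @return a [MatrixWindow-class].
#' @export
matrixWindow <- function(origin, corner, label = "") {
  new("MatrixWindow", origin = as.integer(origin), corner = as.integer(corner),
      label = as.character(label))
}

#' Crop a rectangular window out of a co-occurrence matrix
#'
#' Returns the inclusive submatrix of raw counts; no renormalization is
#' performed, so descriptor code treats the window exactly like a (smaller)
#' co-occurrence matrix.
#'
#' @param m a [CooccurrenceMatrix-class].
#' @param w a [MatrixWindow-class].
#' @return a cropped [CooccurrenceMatrix-class] (`full = FALSE`).
#' @export
cropWindow <- function(m, w) {
  stopifnot(is(m, "CooccurrenceMatrix"), is(w, "MatrixWindow"))
  if (any(w@corner >= dim(m@counts)))
    stop(sprintf("window [%s]-[%s] out of bounds for a %d x %d matrix",
                 paste(w@origin, collapse = ","), paste(w@corner, collapse = ","),
                 nrow(m@counts), ncol(m@counts)))
  sub <- m@counts[(w@origin[1] + 1L):(w@corner[1] + 1L),
                  (w@origin[2] + 1L):(w@corner[2] + 1L), drop = FALSE]
  new("CooccurrenceMatrix", counts = sub, d = m@d, theta = m@theta,
      sourceDims = m@sourceDims, full = FALSE)
}

#' Window presets
#'
#' `wholeWindow()` spans the full matrix. `quadrantWindows()` are the four
#' 128 x 128 quadrants of a 256 x 256 matrix used by the `*sub` variants of
#' the Haralick, run-length, curvature and subspace descriptors.
#' `shapeWindows()` are the twelve overlapping subwindows used by the SHAPE
#' descriptor.
#'
#' @param nLevels matrix size the windows refer to (default 256).
#' @return list of [MatrixWindow-class] objects.
#' @export
wholeWindow <- function(nLevels = 256L) {
  matrixWindow(c(0L, 0L), c(nLevels - 1L, nLevels - 1L), "whole")
}

#' @rdname wholeWindow
#' @export
quadrantWindows <- function(nLevels = 256L) {
  stopifnot(nLevels %% 2L == 0L)
  h <- nLevels %/% 2L
  list(
    matrixWindow(c(0L, 0L), c(h - 1L, h - 1L), "q1"),
    matrixWindow(c(h, h), c(nLevels - 1L, nLevels - 1L), "q2"),
    matrixWindow(c(h, 0L), c(nLevels - 1L, h - 1L), "q3"),
    matrixWindow(c(0L, h), c(h - 1L, nLevels - 1L), "q4")
  )
}

#' @rdname wholeWindow
#' @export
shapeWindows <- function(nLevels = 256L) {
  stopifnot(nLevels == 256L)
  coords <- list(
    c(0, 0, 127, 127), c(128, 128, 255, 255), c(0, 0, 191, 191),
    c(64, 64, 255, 255), c(0, 0, 95, 95), c(31, 31, 95, 95),
    c(63, 63, 127, 127), c(95, 95, 159, 159), c(127, 127, 191, 191),
    c(159, 159, 223, 223), c(191, 191, 255, 255), c(63, 63, 191, 191)
  )
  lapply(seq_along(coords), function(i) {
    z <- coords[[i]]
    matrixWindow(z[1:2], z[3:4], paste0("w", i))
  })
}

#' Write a co-occurrence matrix to a CSV file
#'
#' One matrix per file, row-major, raw counts without header.
#'
#' @param m a [CooccurrenceMatrix-class].
#' @param path output file.
#' @export
writeGlcmCSV <- function(m, path) {
  stopifnot(is(m, "CooccurrenceMatrix"))
  utils::write.table(m@counts, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
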