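# Level-curve (SHAPE) descriptors: the co-occurrence matrix is read as a 3D
# surface, sliced with horizontal planes at fixed heights, and the evolution
# of the largest blob's moment-equivalent ellipse across heights is
# summarized in nine features.

#' Slice a co-occurrence matrix with horizontal planes
#'
#' For each height `h` the binary mask `counts > h` is computed on the raw
#' (unnormalized) counts, its connected components are labeled under
#' 8-connectivity, and the component with the largest pixel count is
#' selected as the main blob (area ties broken by the smallest linear pixel
#' index). The default heights 1, 3, ..., 19 probe the stable low region of
#' the surface.
#'
#' @param m a [CooccurrenceMatrix-class] (raw counts).
#' @param heights thresholds (default `seq(1, 19, by = 2)`).
#' @return list of level slices; each is a list with elements `height`,
#'   `mask` (logical matrix), `nBlobs`, `mainBlob` (2-column matrix of
#'   (row, col) pixel coordinates, 0 rows when empty) and `area`.
#' @export
levelSlices <- function(m, heights = seq(1, 19, by = 2)) {
  stopifnot(is(m, "CooccurrenceMatrix"))
  ct <- m@counts
  lapply(heights, function(h) {
    mask <- ct > h
    if (!any(mask)) {
      return(list(height = h, mask = mask, nBlobs = 0L,
                  mainBlob = matrix(integer(0), 0, 2), area = 0L))
    }
    lab <- label8(mask)
    sizes <- tabulate(lab[lab > 0])
    big <- which(sizes == max(sizes))
    if (length(big) > 1L) {
      # tie: component containing the smallest linear pixel index
      first <- vapply(big, function(b) which(lab == b)[1], numeric(1))
      big <- big[which.min(first)]
    }
    idx <- which(lab == big)
    blob <- cbind(row = (idx - 1L) %% nrow(ct) + 1L,
                  col = (idx - 1L) %/% nrow(ct) + 1L)
    list(height = h, mask = mask, nBlobs = length(sizes),
         mainBlob = blob, area = nrow(blob))
  })
}

#' Moment-equivalent ellipse of a pixel blob
#'
#' Fits the ellipse whose second-order central moments match those of the
#' blob's pixel coordinates. Axis lengths are the full lengths
#' `4 * sqrt(eigenvalue)` of the coordinate covariance (population
#' denominator), which recovers the diameter of a rasterized disc.
#' Orientation is the angle of the major axis from the row axis, in
#' `[-pi/2, pi/2)`.
#'
#' @param blob 2-column matrix of (row, col) pixel coordinates.
#' @return list with `center`, `majorAxis`, `minorAxis`, `orientation`,
#'   `eccentricity`, `area`, `empty`.
#' @export
fitEllipse <- function(blob) {
  if (is.null(blob) || nrow(blob) == 0L) {
    return(list(center = c(0, 0), majorAxis = 0, minorAxis = 0,
                orientation = 0, eccentricity = 0, area = 0L, empty = TRUE))
  }
  n <- nrow(blob)
  ctr <- colMeans(blob)
  dr <- blob[, 1] - ctr[1]
  dc <- blob[, 2] - ctr[2]
  crr <- mean(dr^2); ccc <- mean(dc^2); crc <- mean(dr * dc)
  tr <- crr + ccc
  det <- crr * ccc - crc^2
  disc <- sqrt(max(0, (tr / 2)^2 - det))
  l1 <- tr / 2 + disc
  l2 <- max(0, tr / 2 - disc)
  orientation <- if (abs(crc) < 1e-12 && abs(crr - ccc) < 1e-12) 0
                 else 0.5 * atan2(2 * crc, crr - ccc)
  if (orientation >= pi / 2) orientation <- orientation - pi
  if (orientation < -pi / 2) orientation <- orientation + pi
  major <- 4 * sqrt(l1)
  minor <- 4 * sqrt(l2)
  ecc <- if (major > 0) sqrt(max(0, 1 - (minor / major)^2)) else 0
  list(center = unname(ctr), majorAxis = major, minorAxis = minor,
       orientation = orientation, eccentricity = ecc, area = n, empty = FALSE)
}

#' Names of the nine level-curve evolution features
#' @export
shapeFeatureNames <- c("area_slope", "area_intercept", "ecc_mean", "ecc_slope",
                       "orient_circmean", "centroid_path", "n_nonempty",
                       "mean_blob_count", "area_ratio_low_high")

#' Nine features summarizing the evolution of the level curves
#'
#' Per-level main-blob ellipses are combined into nine deterministic
#' summaries: (1) slope and (2) intercept of the least-squares fit of
#' main-blob area against height; (3) mean and (4) least-squares slope of
#' eccentricity against height; (5) circular mean of the (axial, period-pi)
#' ellipse orientations; (6) total centroid path length across consecutive
#' non-empty levels; (7) number of non-empty levels; (8) mean blob count per
#' level; (9) area ratio between the lowest and highest non-empty levels.
#' When every slice is empty the nine features are zero and the result
#' carries `attr(, "empty") = TRUE`.
#'
#' @param slices result of [levelSlices()].
#' @return named numeric vector of length 9 (see [shapeFeatureNames]).
#' @export
evolutionFeatures <- function(slices) {
  stopifnot(length(slices) >= 1L)
  h <- vapply(slices, `[[`, numeric(1), "height")
  area <- vapply(slices, `[[`, numeric(1), "area")
  nBlobs <- vapply(slices, `[[`, numeric(1), "nBlobs")
  fits <- lapply(slices, function(s) fitEllipse(s$mainBlob))
  nonEmpty <- area > 0
  out <- stats::setNames(numeric(9), shapeFeatureNames)
  if (!any(nonEmpty)) {
    attr(out, "empty") <- TRUE
    return(out)
  }
  lsq <- function(x, y) {   # slope/intercept, 0 slope when < 2 points
    if (length(x) < 2L) return(c(0, if (length(y)) y else 0))
    f <- stats::lm.fit(cbind(1, x), y)
    c(f$coefficients[2], f$coefficients[1])
  }
  hn <- h[nonEmpty]
  areaFit <- lsq(hn, area[nonEmpty])
  ecc <- vapply(fits[nonEmpty], `[[`, numeric(1), "eccentricity")
  eccFit <- lsq(hn, ecc)
  ang <- vapply(fits[nonEmpty], `[[`, numeric(1), "orientation")
  circ <- 0.5 * atan2(mean(sin(2 * ang)), mean(cos(2 * ang)))
  centers <- t(vapply(fits[nonEmpty], `[[`, numeric(2), "center"))
  path <- if (nrow(centers) < 2L) 0 else sum(sqrt(rowSums(diff(centers)^2)))
  out[] <- c(areaFit[1], areaFit[2], mean(ecc), eccFit[1], circ, path,
             sum(nonEmpty), mean(nBlobs),
             area[nonEmpty][1] / area[nonEmpty][sum(nonEmpty)])
  attr(out, "empty") <- FALSE
  out
}

#' SHAPE descriptor: whole matrix plus twelve subwindows
#'
#' For each window (the whole matrix followed by the 12 fixed subwindows of
#' [shapeWindows()]) and each (d, theta) matrix of the set, the nine
#' evolution features are computed and concatenated over the set (9 x 8 =
#' 72 values per window with the default grid). Each window's vector later
#' feeds a separate classifier.
#'
#' @param s a [GlcmSet-class].
#' @param windows list of [MatrixWindow-class]; default whole + 12 SHAPE
#'   subwindows.
#' @param heights slice heights (default `seq(1, 19, by = 2)`).
#' @return named list of numeric vectors, one per window.
#' @export
shDescriptor <- function(s, windows = c(list(wholeWindow(s@nLevels)), shapeWindows(s@nLevels)),
                         heights = seq(1, 19, by = 2)) {
  stopifnot(is(s, "GlcmSet"))
  out <- lapply(windows, function(w) {
    v <- lapply(names(s@matrices), function(nm) {
      m <- cropWindow(s@matrices[[nm]], w)
      fv <- evolutionFeatures(levelSlices(m, heights))
      stats::setNames(as.numeric(fv), sprintf("sh_%s_%s", nm, shapeFeatureNames))
    })
    unlist(v)
  })
  names(out) <- vapply(windows, function(w) w@label, character(1))
  out
}
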