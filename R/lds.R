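# Direct use of the co-occurrence matrix as a descriptor: flatten, PCA,
# keep the smallest basis retaining 99% of the variance.

flattenGLCM <- function(m, normalize = TRUE) {
  ct <- m@counts
  tot <- sum(ct)
  if (normalize && tot > 0) ct <- ct / tot
  as.numeric(ct)    # column-major flattening, fixed order
}

#' Fit a PCA subspace to a set of training co-occurrence matrices
#'
#' Matrices are flattened (after optional count-normalization to
#' probabilities, the default, so image size does not dominate the
#' variance), centered on their mean, and decomposed by principal component
#' analysis. The smallest number of leading components whose cumulative
#' explained variance reaches `varFrac` (0.99 by default) is kept. The
#' model must be fitted on training-fold matrices only; projection of test
#' matrices uses the stored mean and basis.
#'
#' @param mats list of [CooccurrenceMatrix-class] objects of equal shape
#'   (>= 2).
#' @param varFrac variance fraction to retain (default 0.99).
#' @param normalize normalize counts to probabilities before flattening.
#' @param key identifier of the (d, theta, window, scale) slot served.
#' @return a [SubspaceModel-class].
#' @export
fitSubspace <- function(mats, varFrac = 0.99, normalize = TRUE, key = "") {
  if (length(mats) < 2L) stop("at least 2 training matrices are required")
  shp <- dim(mats[[1]]@counts)
  if (!all(vapply(mats, function(m) identical(dim(m@counts), shp), logical(1))))
    stop("all training matrices must share the same shape")
  X <- do.call(rbind, lapply(mats, flattenGLCM, normalize = normalize))
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2
  totVar <- sum(ev)
  if (totVar < 1e-300) {
    warning("zero-variance training data: keeping a single component")
    basis <- matrix(0, ncol(X), 1)
    basis[1, 1] <- 1
    return(new("SubspaceModel", center = ctr, basis = basis,
               varianceExplained = 1, retainedVariance = 1,
               nComponents = 1L, normalize = normalize, key = key))
  }
  frac <- ev / totVar
  k <- which(cumsum(frac) >= varFrac - 1e-12)[1]
  new("SubspaceModel", center = ctr,
      basis = sv$v[, seq_len(k), drop = FALSE],
      varianceExplained = frac[seq_len(k)],
      retainedVariance = sum(frac[seq_len(k)]),
      nComponents = as.integer(k), normalize = normalize, key = key)
}

#' Project a co-occurrence matrix onto a fitted subspace
#'
#' @param m a [CooccurrenceMatrix-class] whose shape matches the model.
#' @param model a [SubspaceModel-class].
#' @return numeric vector of length `model@nComponents`.
#' @export
projectSubspace <- function(m, model) {
  stopifnot(is(m, "CooccurrenceMatrix"), is(model, "SubspaceModel"))
  v <- flattenGLCM(m, normalize = model@normalize)
  if (length(v) != length(model@center))
    stop("matrix shape does not match the subspace model")
  as.numeric((v - model@center) %*% model@basis)
}

#' Persist / restore a subspace model as a portable text archive
#'
#' @param model a [SubspaceModel-class].
#' @param path output file (RDS-free plain text: JSON with numeric arrays).
#' @export
writeSubspaceModel <- function(model, path) {
  obj <- list(center = model@center, basis = model@basis,
              varianceExplained = model@varianceExplained,
              retainedVariance = model@retainedVariance,
              nComponents = model@nComponents, normalize = model@normalize,
              key = model@key)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeSubspaceModel
#' @export
readSubspaceModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  new("SubspaceModel", center = as.numeric(obj$center),
      basis = matrix(as.numeric(obj$basis), ncol = obj$nComponents),
      varianceExplained = as.numeric(obj$varianceExplained),
      retainedVariance = as.numeric(obj$retainedVariance),
      nComponents = as.integer(obj$nComponents),
      normalize = as.logical(obj$normalize), key = as.character(obj$key))
}
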