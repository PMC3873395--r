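# Per-panel SVM scoring, z-score normalization, weighted-sum fusion and
# one-vs-all AUC evaluation under stratified 5-fold cross-validation.
# Everything that is fitted (scorers, normalizers, subspace models) is
# fitted on the training fold only.

#' Default SVM hyperparameter grid
#'
#' Linear, polynomial and radial basis function kernels with
#' C in \{0.01, 0.1, 1, 10, 100\}, RBF gamma in 2^-5..2^3 and polynomial
#' degree in \{2, 3\}. The best configuration is chosen per training
#' partition by inner 5-fold cross-validation.
#'
#' @return list of configuration lists (kernel, cost, gamma, degree).
#' @export
defaultSvmGrid <- function() {
  costs <- c(0.01, 0.1, 1, 10, 100)
  grid <- list()
  for (C in costs) grid[[length(grid) + 1L]] <- list(kernel = "linear", cost = C)
  for (C in costs) for (g in 2^(-5:3))
    grid[[length(grid) + 1L]] <- list(kernel = "radial", cost = C, gamma = g)
  for (C in costs) for (dg in 2:3)
    grid[[length(grid) + 1L]] <- list(kernel = "polynomial", cost = C, degree = dg)
  grid
}

# Fit one-vs-all SVMs for one configuration on standardized features.
# Returns per-class models plus orientation signs chosen on training data.
fitOvaSvm <- function(xs, y, config) {
  classes <- levels(y)
  svmArgs <- list(kernel = config$kernel, cost = config$cost, scale = FALSE)
  if (!is.null(config$gamma)) svmArgs$gamma <- config$gamma
  if (!is.null(config$degree)) svmArgs$degree <- config$degree
  models <- list(); signs <- numeric(length(classes))
  for (k in seq_along(classes)) {
    y2 <- factor(ifelse(y == classes[k], "pos", "neg"), levels = c("pos", "neg"))
    fit <- do.call(e1071::svm, c(list(x = xs, y = y2), svmArgs))
    dec <- attr(stats::predict(fit, xs, decision.values = TRUE),
                "decision.values")[, 1]
    signs[k] <- if (mean(dec[y2 == "pos"]) >= mean(dec[y2 == "neg"])) 1 else -1
    models[[k]] <- fit
    if (length(classes) == 2L) {   # second class is the mirror image
      models[[2L]] <- fit
      signs[2L] <- -signs[1L]
      break
    }
  }
  list(models = models, signs = signs, classes = classes)
}

scoreOvaSvm <- function(ova, xs) {
  K <- length(ova$classes)
  out <- matrix(0, nrow(xs), K, dimnames = list(NULL, ova$classes))
  for (k in seq_len(K)) {
    if (K == 2L && k == 2L) {  # binary: the second class mirrors the first
      out[, 2L] <- -out[, 1L]
      break
    }
    dec <- attr(stats::predict(ova$models[[k]], xs, decision.values = TRUE),
                "decision.values")[, 1]
    out[, k] <- ova$signs[k] * dec
  }
  out
}

#' Train an SVM scorer with inner cross-validated model selection
#'
#' Standardizes the features (training statistics), evaluates every grid
#' configuration by mean one-vs-all AUC over stratified inner folds of the
#' training partition only, fits one-vs-all SVMs with the winning
#' configuration on the full partition, and returns an object that emits
#' per-class decision scores for new samples via [scoreSamples()].
#'
#' @param x numeric feature matrix (samples x features).
#' @param labels class labels (>= 2 classes present).
#' @param innerFolds inner CV folds (default 5, reduced if classes are
#'   smaller).
#' @param grid hyperparameter grid (default [defaultSvmGrid()]).
#' @param seed seed for the inner fold assignment.
#' @return an object of class `cooctexScorer`.
#' @export
trainScorer <- function(x, labels, innerFolds = 5L, grid = defaultSvmGrid(),
                        seed = 1L) {
  x <- as.matrix(x)
  labels <- factor(labels)
  if (nlevels(labels) < 2L) stop("training data contains a single class")
  bad <- !apply(is.finite(x), 2, all)
  if (any(bad))
    stop("non-finite feature values in descriptor column(s): ",
         paste(utils::head(colnames(x)[bad], 5), collapse = ", "))
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2, ctr)^2))
  scl[scl < 1e-12] <- Inf
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  innerFolds <- max(2L, min(innerFolds, min(table(labels))))
  fold <- stratifiedFolds(labels, innerFolds, seed)
  perf <- vapply(grid, function(cfg) {
    aucs <- vapply(seq_len(innerFolds), function(f) {
      tr <- fold != f
      if (nlevels(droplevels(labels[tr])) < 2L) return(NA_real_)
      ova <- fitOvaSvm(xs[tr, , drop = FALSE], labels[tr], cfg)
      sc <- scoreOvaSvm(ova, xs[!tr, , drop = FALSE])
      aucOVA(sc, labels[!tr], quiet = TRUE)
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(perf)   # ties resolve to the earliest grid entry
  cfg <- grid[[best]]
  ova <- fitOvaSvm(xs, labels, cfg)
  structure(list(ova = ova, config = cfg, center = ctr, scale = scl,
                 classes = levels(labels), innerAuc = perf[best]),
            class = "cooctexScorer")
}

#' Score new samples with a trained scorer
#'
#' @param scorer a `cooctexScorer` from [trainScorer()].
#' @param x feature matrix with the training columns.
#' @return numeric matrix samples x classes of decision scores.
#' @export
scoreSamples <- function(scorer, x) {
  x <- as.matrix(x)
  xs <- sweep(sweep(x, 2, scorer$center), 2, scorer$scale, "/")
  scoreOvaSvm(scorer$ova, xs)
}

#' @export
print.cooctexScorer <- function(x, ...) {
  cat(sprintf("cooctexScorer: %s kernel (C = %g%s), %d classes, inner AUC %.3f\n",
              x$config$kernel, x$config$cost,
              if (!is.null(x$config$gamma)) sprintf(", gamma = %g", x$config$gamma)
              else if (!is.null(x$config$degree)) sprintf(", degree = %d", x$config$degree)
              else "",
              length(x$classes), x$innerAuc))
  invisible(x)
}

#' Construct a score panel
#'
#' @param scores samples x classes score matrix.
#' @param source identifier of the producing panel.
#' @param normalized whether the scores are already column z-scored.
#' @return a [ScorePanel-class].
#' @export
scorePanel <- function(scores, source = "", normalized = FALSE) {
  new("ScorePanel", scores = as.matrix(scores), source = source,
      normalized = normalized)
}

#' Normalize a score panel to column mean 0 and standard deviation 1
#'
#' Population standard deviation; constant columns map to zero. Applying
#' the function twice is the same as applying it once.
#'
#' @param p a [ScorePanel-class].
#' @return a normalized [ScorePanel-class].
#' @export
normalizePanel <- function(p) {
  stopifnot(is(p, "ScorePanel"))
  new("ScorePanel", scores = zscoreColumns(p@scores), source = p@source,
      normalized = TRUE)
}

#' Fuse score panels by weighted sum
#'
#' `fused[s, c] = sum_k w_k * panel_k[s, c]`; the panels must be aligned on
#' samples and classes (and are expected to be normalized first when they
#' come from different descriptors).
#'
#' @param panels list of [ScorePanel-class].
#' @param weights positive weights, one per panel.
#' @return a [ScorePanel-class] (not normalized).
#' @export
fusePanels <- function(panels, weights = rep(1, length(panels))) {
  stopifnot(length(panels) >= 1L, length(weights) == length(panels),
            all(weights > 0))
  dims <- lapply(panels, function(p) dim(p@scores))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("panels are not aligned on samples and classes")
  acc <- weights[1] * panels[[1]]@scores
  for (k in seq_along(panels)[-1]) acc <- acc + weights[k] * panels[[k]]@scores
  new("ScorePanel", scores = acc,
      source = paste0("fused(", paste(vapply(panels, function(p) p@source,
                                             character(1)), collapse = "+"), ")"),
      normalized = FALSE)
}

#' One-vs-all AUC
#'
#' Per-class ranking AUC (class vs rest, ties counted 0.5) averaged over
#' the classes present in `labels`; classes with a score column but absent
#' from the labels are skipped with a warning.
#'
#' @param scores samples x classes matrix (or a [ScorePanel-class]).
#' @param labels class labels; matched to `colnames(scores)` when named,
#'   otherwise by factor level order.
#' @param quiet suppress the absent-class warning.
#' @return average AUC in `[0, 1]`.
#' @export
aucOVA <- function(scores, labels, quiet = FALSE) {
  if (is(scores, "ScorePanel")) scores <- scores@scores
  scores <- as.matrix(scores)
  labels <- factor(labels)
  cls <- colnames(scores)
  if (is.null(cls)) {
    if (ncol(scores) != nlevels(labels))
      stop("unnamed score columns must match the number of label levels")
    cls <- levels(labels)
  }
  aucs <- numeric(0)
  for (k in seq_along(cls)) {
    pos <- labels == cls[k]
    if (!any(pos)) {
      if (!quiet) warning("class absent from labels, skipped: ", cls[k])
      next
    }
    if (all(pos)) next
    r <- rank(scores[, k])
    n1 <- sum(pos); n0 <- sum(!pos)
    aucs <- c(aucs, (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0))
  }
  if (length(aucs) == 0L) stop("no class with both positive and negative samples")
  mean(aucs)
}

#' Stratified cross-validation plan
#'
#' @param labels class labels.
#' @param nFolds number of folds (default 5).
#' @param seed fold-assignment seed.
#' @return list with `fold` (integer assignment per sample), `nFolds`,
#'   `seed`.
#' @export
cvPlan <- function(labels, nFolds = 5L, seed = 1L) {
  labels <- factor(labels)
  if (any(table(labels) < 2L))
    warning("a class has fewer than 2 samples; it will be absent from some training folds")
  list(fold = stratifiedFolds(labels, nFolds, seed), nFolds = as.integer(nFolds),
       seed = as.integer(seed))
}
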