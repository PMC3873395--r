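# Experiment orchestration: descriptor panels -> per-fold SVM scores ->
# normalization -> weighted-sum fusion -> mean outer-fold one-vs-all AUC.
#
# Method ids follow the descriptor families: HR/GR/CU/LD/SH extract from the
# whole matrix at the original scale; the *sub variants add subwindows of
# the co-occurrence matrix; the *sca variants add the two Gaussian-smoothed
# scales; SUM2/WS2/W2/W3 fuse the score panels of several families.

#' Supported method identifiers
#' @export
methodIds <- c("HR", "HRsub", "HRsca", "GR", "GRsub", "GRsca",
               "CU", "CUsub", "CUsca", "LD", "LDsub", "LDsca",
               "SH", "SHsub", "SHsca", "SUM2", "WS2", "W2", "W3")

# Window presets per family: HAR/GL/CU/LD use whole + 4 quadrants, SH uses
# whole + its 12 printed subwindows.
familyWindows <- function(family, variant, nLevels = 256L) {
  whole <- list(wholeWindow(nLevels))
  if (variant == "base") return(whole)
  if (family == "SH") c(whole, shapeWindows(nLevels))
  else c(whole, quadrantWindows(nLevels))
}

# Panel weights. For sub variants: whole 4, quadrants 1 (SH: first five
# windows 1, remaining eight 0.5). For sca variants of HAR/GL/CU/LD the
# scale rule replaces the window rule (original-scale panels 4, filtered 1);
# for SHsca the window weight is multiplied by the scale weight.
panelWeight <- function(family, variant, windowIdx, scaleIdx) {
  scaleW <- if (scaleIdx == 1L) 4 else 1
  if (family == "SH") {
    winW <- if (windowIdx <= 5L) 1 else 0.5
    if (variant == "sca") winW * scaleW else winW
  } else {
    winW <- if (windowIdx == 1L) 4 else 1
    switch(variant, base = 1, sub = winW, sca = scaleW)
  }
}

methodPlan <- function(method) {
  if (!method %in% methodIds) stop("unknown method: ", method)
  if (method %in% c("SUM2", "WS2", "W2", "W3")) {
    members <- switch(method,
      SUM2 = list(HRsca = 1, GRsca = 1),
      WS2  = list(HRsca = 2, GRsca = 1),
      W2   = list(SUM2 = 2, SHsca = 1),
      W3   = list(SUM2 = 3, SHsca = 1))
    return(list(type = "composite", members = members))
  }
  family <- c(HR = "HAR", GR = "GL", CU = "CU", LD = "LD", SH = "SH")[
    substr(method, 1, 2)]
  variant <- if (endsWith(method, "sub")) "sub"
             else if (endsWith(method, "sca")) "sca" else "base"
  list(type = "leaf", family = unname(family), variant = variant)
}

# Descriptor feature vector for one family / glcm set / window.
familyFeatures <- function(family, set, window, opts) {
  switch(family,
    HAR = suppressWarnings(harDescriptor(set, window)),
    GL  = glDescriptor(set, window, rlLevels = opts$rlLevels),
    CU  = cuDescriptor(set, window, radii = opts$cuRadii, nBins = opts$cuBins),
    SH  = {
      v <- lapply(names(set@matrices), function(nm) {
        m <- cropWindow(set@matrices[[nm]], window)
        fv <- evolutionFeatures(levelSlices(m))
        stats::setNames(as.numeric(fv), sprintf("sh_%s_%s", nm, shapeFeatureNames))
      })
      unlist(v)
    },
    stop("no direct features for family ", family))
}

#' Default options for [runExperiment()]
#'
#' Run-length quantization levels, curvature radii and bins, the SVM
#' hyperparameter grid, inner CV folds, the LD variance-retention fraction
#' and the LD memory budget (bytes).
#'
#' @return named list of options.
#' @export
defaultExperimentOpts <- function() {
  list(rlLevels = 16L, cuRadii = c(3, 5, 7), cuBins = 8L,
       svmGrid = defaultSvmGrid(), innerFolds = 5L,
       ldVarFrac = 0.99, ldMemoryBudget = 2e9)
}

#' Shared descriptor cache for several [runExperiment()] calls
#'
#' Methods evaluated on the same images recompute nothing when they share a
#' context: co-occurrence sets and per-panel feature matrices are cached in
#' the returned environment.
#'
#' @param images list of [GrayImage-class] objects.
#' @param labels class labels.
#' @param opts options list, see [defaultExperimentOpts()].
#' @return an environment to pass as `ctx` to [runExperiment()].
#' @export
experimentContext <- function(images, labels, opts = defaultExperimentOpts()) {
  env <- new.env(parent = emptyenv())
  env$images <- images
  env$labels <- factor(labels)
  env$opts <- opts
  env$glcmSets <- list()       # [[scaleName]][[imageIdx]]
  env$features <- list()       # [[family|window|scale]] feature matrix
  env$leafScores <- list()     # memoized per-method fold scores
  env
}

scaleNames <- c("original", "k3", "k5")

getGlcmSets <- function(ctx, scaleName) {
  if (!is.null(ctx$glcmSets[[scaleName]])) return(ctx$glcmSets[[scaleName]])
  sets <- lapply(ctx$images, function(img) {
    im <- if (scaleName == "original") img
          else gaussianStack(img)[[scaleName]]
    glcmSet(im)
  })
  ctx$glcmSets[[scaleName]] <- sets
  sets
}

getPanelFeatures <- function(ctx, family, window, scaleName) {
  key <- paste(family, window@label, scaleName, sep = "|")
  if (!is.null(ctx$features[[key]])) return(ctx$features[[key]])
  sets <- getGlcmSets(ctx, scaleName)
  feat <- t(vapply(sets, function(s) familyFeatures(family, s, window, ctx$opts),
                   familyFeatures(family, sets[[1]], window, ctx$opts)))
  ctx$features[[key]] <- feat
  feat
}

# Cropped, probability-normalized flattened matrices for the LD family:
# one matrix (images x flattened-window) per (d, theta) slot.
getLdSlotMatrices <- function(ctx, window, scaleName) {
  key <- paste("LDraw", window@label, scaleName, sep = "|")
  if (!is.null(ctx$features[[key]])) return(ctx$features[[key]])
  sets <- getGlcmSets(ctx, scaleName)
  slotNames <- names(sets[[1]]@matrices)
  p <- prod(window@corner - window@origin + 1L)
  need <- length(sets) * p * length(slotNames) * 8
  if (need > ctx$opts$ldMemoryBudget)
    stop(sprintf("memory guard: LD on this input needs about %.1f GB (budget %.1f GB)",
                 need / 1e9, ctx$opts$ldMemoryBudget / 1e9))
  slots <- lapply(slotNames, function(nm) {
    t(vapply(sets, function(s)
      flattenGLCM(cropWindow(s@matrices[[nm]], window), normalize = TRUE),
      numeric(p)))
  })
  names(slots) <- slotNames
  ctx$features[[key]] <- slots
  slots
}

# PCA on a plain flattened matrix; returns center/basis like fitSubspace.
fitSubspaceFlat <- function(X, varFrac) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr)
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2
  totVar <- sum(ev)
  if (totVar < 1e-300) {
    basis <- matrix(0, ncol(X), 1); basis[1, 1] <- 1
    return(list(center = ctr, basis = basis))
  }
  k <- which(cumsum(ev / totVar) >= varFrac - 1e-12)[1]
  list(center = ctr, basis = sv$v[, seq_len(k), drop = FALSE])
}

# Per-fold normalized-and-fused scores of a leaf method.
leafFoldScores <- function(ctx, method, fold, nFolds, seed) {
  plan <- methodPlan(method)
  windows <- familyWindows(plan$family, plan$variant)
  scales <- if (plan$variant == "sca") scaleNames else scaleNames[1]
  labels <- ctx$labels
  K <- nlevels(labels)
  folds <- lapply(seq_len(nFolds), function(f) {
    list(train = which(fold != f), test = which(fold == f),
         fusedTrain = matrix(0, sum(fold != f), K),
         fusedTest = matrix(0, sum(fold == f), K), panels = list())
  })
  for (si in seq_along(scales)) {
    for (wi in seq_along(windows)) {
      w <- panelWeight(plan$family, plan$variant, wi, si)
      panelId <- sprintf("%s|%s|%s", plan$family, windows[[wi]]@label, scales[si])
      if (plan$family == "LD") {
        slots <- getLdSlotMatrices(ctx, windows[[wi]], scales[si])
      } else {
        feat <- getPanelFeatures(ctx, plan$family, windows[[wi]], scales[si])
      }
      for (f in seq_len(nFolds)) {
        tr <- folds[[f]]$train; te <- folds[[f]]$test
        if (plan$family == "LD") {
          projTr <- list(); projTe <- list()
          for (nm in names(slots)) {
            mdl <- fitSubspaceFlat(slots[[nm]][tr, , drop = FALSE],
                                   ctx$opts$ldVarFrac)
            projTr[[nm]] <- sweep(slots[[nm]][tr, , drop = FALSE], 2, mdl$center) %*% mdl$basis
            projTe[[nm]] <- sweep(slots[[nm]][te, , drop = FALSE], 2, mdl$center) %*% mdl$basis
          }
          xtr <- do.call(cbind, projTr); xte <- do.call(cbind, projTe)
          colnames(xtr) <- colnames(xte) <- paste0("ld", seq_len(ncol(xtr)))
        } else {
          xtr <- feat[tr, , drop = FALSE]; xte <- feat[te, , drop = FALSE]
        }
        scorer <- trainScorer(xtr, labels[tr], innerFolds = ctx$opts$innerFolds,
                              grid = ctx$opts$svmGrid, seed = seed + f)
        sTr <- scoreSamples(scorer, xtr)
        sTe <- scoreSamples(scorer, xte)
        mu <- colMeans(sTr)
        sdv <- sqrt(colMeans(sweep(sTr, 2, mu)^2))
        sdv[sdv < 1e-12] <- Inf
        nTr <- sweep(sweep(sTr, 2, mu), 2, sdv, "/")
        nTe <- sweep(sweep(sTe, 2, mu), 2, sdv, "/")
        folds[[f]]$fusedTrain <- folds[[f]]$fusedTrain + w * nTr
        folds[[f]]$fusedTest <- folds[[f]]$fusedTest + w * nTe
        folds[[f]]$panels[[panelId]] <- list(kernel = scorer$config$kernel,
                                             cost = scorer$config$cost,
                                             weight = w)
      }
    }
  }
  folds
}

methodFoldScores <- function(ctx, method, fold, nFolds, seed) {
  key <- sprintf("%s|seed%d", method, seed)
  if (!is.null(ctx$leafScores[[key]])) return(ctx$leafScores[[key]])
  plan <- methodPlan(method)
  res <- if (plan$type == "leaf") {
    leafFoldScores(ctx, method, fold, nFolds, seed)
  } else {
    memberRes <- lapply(names(plan$members), function(m)
      methodFoldScores(ctx, m, fold, nFolds, seed))
    weights <- unlist(plan$members)
    folds <- lapply(seq_len(nFolds), function(f) {
      base <- memberRes[[1]][[f]]
      fusedTrain <- matrix(0, length(base$train), ncol(base$fusedTrain))
      fusedTest <- matrix(0, length(base$test), ncol(base$fusedTest))
      panels <- list()
      for (mi in seq_along(memberRes)) {
        mf <- memberRes[[mi]][[f]]
        mu <- colMeans(mf$fusedTrain)
        sdv <- sqrt(colMeans(sweep(mf$fusedTrain, 2, mu)^2))
        sdv[sdv < 1e-12] <- Inf
        fusedTrain <- fusedTrain + weights[mi] *
          sweep(sweep(mf$fusedTrain, 2, mu), 2, sdv, "/")
        fusedTest <- fusedTest + weights[mi] *
          sweep(sweep(mf$fusedTest, 2, mu), 2, sdv, "/")
        panels <- c(panels, mf$panels)
      }
      list(train = base$train, test = base$test, fusedTrain = fusedTrain,
           fusedTest = fusedTest, panels = panels)
    })
    folds
  }
  ctx$leafScores[[key]] <- res
  res
}

#' Run a cross-validated texture classification experiment
#'
#' Extracts the descriptor panels required by `method`, trains one SVM per
#' panel inside each outer training fold (model selection by inner
#' cross-validation), z-normalizes each panel's scores with training-fold
#' statistics, fuses them by the method's weighted-sum rule, and reports
#' the mean one-vs-all AUC over the outer test folds. All fitted
#' components (scorers, normalizers, PCA subspaces of the LD family) see
#' training-fold data only.
#'
#' @param images list of [GrayImage-class] objects.
#' @param labels class labels, one per image.
#' @param method a method id (see [methodIds]).
#' @param nFolds outer folds (default 5).
#' @param seed seed for fold assignment and inner model selection.
#' @param opts options list (see `defaultExperimentOpts`): run-length
#'   levels, curvature radii/bins, SVM grid, inner folds, LD variance
#'   fraction and memory budget.
#' @param ctx optional shared context from [experimentContext()] to reuse
#'   descriptor caches across methods.
#' @return list with `method`, `auc` (mean outer-fold AUC), `aucPerFold`,
#'   and `foldLog` (per fold: test indices, panel kernels and weights).
#' @examples
#' \donttest{
#' ds <- makeDataset(10, list(
#'   a = textureSpec(1, "correlated_noise", size = c(32, 32), rho = 0.2),
#'   b = textureSpec(2, "correlated_noise", size = c(32, 32), rho = 0.8)))
#' runExperiment(ds$images, ds$labels, "HR", seed = 7)$auc
#' }
#' @export
runExperiment <- function(images, labels, method, nFolds = 5L, seed = 1L,
                          opts = defaultExperimentOpts(), ctx = NULL) {
  stopifnot(length(images) == length(labels))
  if (is.null(ctx)) ctx <- experimentContext(images, labels, opts)
  labels <- ctx$labels
  plan <- cvPlan(labels, nFolds, seed)
  folds <- methodFoldScores(ctx, method, plan$fold, nFolds, seed)
  aucPerFold <- vapply(seq_len(nFolds), function(f) {
    sc <- folds[[f]]$fusedTest
    colnames(sc) <- levels(labels)
    aucOVA(sc, labels[folds[[f]]$test], quiet = TRUE)
  }, numeric(1))
  foldLog <- lapply(seq_len(nFolds), function(f)
    list(fold = f, test = folds[[f]]$test, panels = folds[[f]]$panels))
  list(method = method, auc = mean(aucPerFold), aucPerFold = aucPerFold,
       foldLog = foldLog)
}
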