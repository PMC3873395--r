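# Cross-validated experiment orchestration on small synthetic datasets.
# A reduced SVM grid keeps the runtime modest; grid contents do not change
# the mechanics under test.

tinyOpts <- function() {
  o <- defaultExperimentOpts()
  o$svmGrid <- list(list(kernel = "linear", cost = 1),
                    list(kernel = "radial", cost = 10, gamma = 0.05))
  o$innerFolds <- 3L
  o
}

arDataset <- function(nPerClass = 8, size = 24, seed = 13) {
  makeDataset(nPerClass, list(
    low = textureSpec(1, "correlated_noise", size = c(size, size), rho = 0.2),
    high = textureSpec(2, "correlated_noise", size = c(size, size), rho = 0.8)),
    seed = seed)
}

test_that("panel composition matches the method definitions", {
  expect_length(familyWindows <- cooctex:::familyWindows("HAR", "sub"), 5L)
  expect_length(cooctex:::familyWindows("SH", "sub"), 13L)
  # HRsca: 5 windows x 3 scales = 15 panels; original-scale weight 4
  expect_equal(cooctex:::panelWeight("HAR", "sca", 1, 1), 4)
  expect_equal(cooctex:::panelWeight("HAR", "sca", 3, 2), 1)
  expect_equal(cooctex:::panelWeight("HAR", "sub", 1, 1), 4)
  expect_equal(cooctex:::panelWeight("HAR", "sub", 2, 1), 1)
  # SHsub: first five windows weight 1, remaining eight 0.5
  expect_equal(cooctex:::panelWeight("SH", "sub", 5, 1), 1)
  expect_equal(cooctex:::panelWeight("SH", "sub", 6, 1), 0.5)
  # composite presets
  p <- cooctex:::methodPlan("W3")
  expect_equal(p$members, list(SUM2 = 3, SHsca = 1))
  expect_equal(cooctex:::methodPlan("WS2")$members, list(HRsca = 2, GRsca = 1))
  expect_error(cooctex:::methodPlan("nope"), "unknown method")
})

test_that("separable textures are classified nearly perfectly", {
  ds <- arDataset()
  res <- runExperiment(ds$images, ds$labels, "HR", seed = 3, opts = tinyOpts())
  expect_gte(res$auc, 0.95)
  expect_length(res$aucPerFold, 5L)
  # HRsub stays within a small margin of HR on the same data
  ctx <- experimentContext(ds$images, ds$labels, tinyOpts())
  res2 <- runExperiment(ds$images, ds$labels, "HRsub", seed = 3,
                        opts = tinyOpts(), ctx = ctx)
  expect_gte(res2$auc, res$auc - 0.03)
  expect_equal(length(res2$foldLog[[1]]$panels), 5L)
})

test_that("identical class distributions give chance-level AUC", {
  ds <- makeDataset(10, list(
    a = textureSpec(1, "correlated_noise", size = c(24, 24), rho = 0.5),
    b = textureSpec(2, "correlated_noise", size = c(24, 24), rho = 0.5)),
    seed = 17)
  res <- runExperiment(ds$images, ds$labels, "HR", seed = 5, opts = tinyOpts())
  expect_gt(res$auc, 0.2)
  expect_lt(res$auc, 0.8)
})

test_that("experiment results are reproducible under a fixed seed", {
  ds <- arDataset(nPerClass = 6, size = 16, seed = 19)
  r1 <- runExperiment(ds$images, ds$labels, "HR", seed = 11, opts = tinyOpts())
  r2 <- runExperiment(ds$images, ds$labels, "HR", seed = 11, opts = tinyOpts())
  expect_identical(r1$aucPerFold, r2$aucPerFold)
})

test_that("shuffling test-fold labels cannot leak into trained panels", {
  ds <- arDataset(nPerClass = 6, size = 16, seed = 23)
  fold <- cvPlan(ds$labels, 5, seed = 7)$fold
  test1 <- which(fold == 1)
  # train a scorer on fold-1 training data, then again after permuting the
  # held-out labels: the fitted panel must be unchanged
  feat <- t(vapply(ds$images,
                   function(im) suppressWarnings(harDescriptor(glcmSet(im))),
                   numeric(104)))
  tr <- setdiff(seq_along(ds$labels), test1)
  s1 <- trainScorer(feat[tr, ], ds$labels[tr], grid = tinyOpts()$svmGrid,
                    seed = 7)
  labShuffled <- ds$labels
  labShuffled[test1] <- sample(labShuffled[test1])
  s2 <- trainScorer(feat[tr, ], labShuffled[tr], grid = tinyOpts()$svmGrid,
                    seed = 7)
  expect_identical(s1$config, s2$config)
  expect_equal(scoreSamples(s1, feat[test1, ]), scoreSamples(s2, feat[test1, ]))
})
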