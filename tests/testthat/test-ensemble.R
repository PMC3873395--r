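smallGrid <- function() {
  list(list(kernel = "linear", cost = 1),
       list(kernel = "radial", cost = 1, gamma = 0.1))
}

test_that("panel normalization z-scores columns with population sd", {
  p <- scorePanel(cbind(a = c(1, 2, 3), b = c(5, 5, 5)))
  n <- normalizePanel(p)
  expect_equal(panelScores(n)[, "a"], c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)
  expect_equal(panelScores(n)[, "b"], c(0, 0, 0))      # constant -> zeros
  # idempotence
  expect_equal(panelScores(normalizePanel(n)), panelScores(n),
               tolerance = 1e-12)
})

test_that("fusion is the weighted elementwise sum of aligned panels", {
  A <- scorePanel(matrix(1:6, 3, 2), source = "A")
  B <- scorePanel(matrix(seq(2, 12, 2), 3, 2), source = "B")
  f <- fusePanels(list(A, B), c(2, 1))
  expect_equal(panelScores(f), 2 * panelScores(A) + panelScores(B))
  # all weights 1 on identical panels: |panels| times the panel
  f3 <- fusePanels(list(A, A, A))
  expect_equal(panelScores(f3), 3 * panelScores(A))
  expect_error(fusePanels(list(A, scorePanel(matrix(1:4, 2, 2))), c(1, 1)),
               "aligned")
  expect_error(fusePanels(list(A), 0), "weights")
})

test_that("one-vs-all AUC matches hand counts and the pairwise oracle", {
  # 3 concordant pairs out of 4: AUC 0.75
  sc <- cbind(pos = c(0.9, 0.8, 0.3, 0.2))
  lab <- c("pos", "neg", "pos", "neg")
  expect_equal(aucOVA(sc, factor(lab, levels = c("pos", "neg"))), 0.75)

  # perfect ordering and complete ties
  expect_equal(aucOVA(cbind(pos = 4:1), factor(c("pos", "pos", "neg", "neg"),
               levels = c("pos", "neg"))), 1)
  expect_equal(aucOVA(cbind(pos = rep(1, 6)),
                      factor(rep(c("pos", "neg"), 3), levels = c("pos", "neg"))),
               0.5)

  # brute-force concordance oracle on random multiclass fixtures
  for (seed in 1:6) {
    set.seed(seed)
    n <- sample(10:50, 1)
    K <- sample(2:4, 1)
    scores <- matrix(rnorm(n * K), n, K,
                     dimnames = list(NULL, paste0("c", 1:K)))
    labels <- factor(sample(paste0("c", 1:K), n, TRUE),
                     levels = paste0("c", 1:K))
    if (nlevels(droplevels(labels)) < 2) next
    expect_equal(suppressWarnings(aucOVA(scores, labels)),
                 naiveAucOVA(scores, labels), tolerance = 1e-12)
  }

  # multiplying all scores by a positive constant leaves the AUC unchanged
  sc <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  lab <- factor(rep(c("a", "b"), 10))
  expect_equal(aucOVA(sc, lab), aucOVA(7 * sc, lab))

  # binary case agrees with an established ROC implementation
  skip_if_not_installed("pROC")
  set.seed(9)
  s <- rnorm(40)
  lab <- factor(sample(rep(c("a", "b"), 20)), levels = c("a", "b"))
  ref <- as.numeric(pROC::auc(pROC::roc(response = lab, predictor = s,
                                        levels = c("b", "a"), direction = "<",
                                        quiet = TRUE)))
  expect_equal(aucOVA(cbind(a = s, b = -s), lab), ref, tolerance = 1e-12)
})

test_that("the SVM scorer separates separable data and validates inputs", {
  set.seed(5)
  x <- rbind(matrix(rnorm(60, 0), 30, 2), matrix(rnorm(60, 6), 30, 2))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("a", "b"), each = 30)
  sc <- trainScorer(x, y, grid = smallGrid(), seed = 3)
  expect_equal(aucOVA(scoreSamples(sc, x), factor(y)), 1)

  expect_error(trainScorer(x, rep("a", 60), grid = smallGrid()),
               "single class")
  xb <- x; xb[1, 1] <- NaN
  expect_error(trainScorer(xb, y, grid = smallGrid()), "f1")
})

test_that("scorer training depends on the training data only", {
  set.seed(11)
  x <- matrix(rnorm(200), 50, 4)
  colnames(x) <- paste0("f", 1:4)
  y <- rep(c("a", "b"), 25)
  s1 <- trainScorer(x, y, grid = smallGrid(), seed = 9)
  s2 <- trainScorer(x, y, grid = smallGrid(), seed = 9)
  expect_identical(s1$config, s2$config)
  # scoring two different "test" sets does not alter the scorer
  t1 <- matrix(rnorm(40), 10, 4); t2 <- matrix(rnorm(40, 5), 10, 4)
  colnames(t1) <- colnames(t2) <- colnames(x)
  invisible(scoreSamples(s1, t1))
  expect_identical(s1$config, s2$config)
  expect_equal(scoreSamples(s1, t2), scoreSamples(s2, t2))
})

test_that("label permutation drives the scorer to chance level", {
  set.seed(23)
  n <- 200
  x <- matrix(rnorm(n * 5), n, 5)
  colnames(x) <- paste0("f", 1:5)
  y <- sample(rep(c("a", "b"), n / 2))
  fold <- rep(1:5, length.out = n)
  aucs <- vapply(1:5, function(f) {
    tr <- fold != f
    sc <- trainScorer(x[tr, ], y[tr], grid = smallGrid(), seed = f)
    aucOVA(scoreSamples(sc, x[!tr, ]), factor(y[!tr], levels = c("a", "b")))
  }, numeric(1))
  expect_gt(mean(aucs), 0.3)
  expect_lt(mean(aucs), 0.7)
})

test_that("fusing two informative noisy panels preserves or improves AUC", {
  set.seed(37)
  n <- 500
  truth <- rep(c(1, 0), each = n / 2)
  lab <- factor(ifelse(truth == 1, "a", "b"), levels = c("a", "b"))
  mk <- function() {
    s <- truth * 1.2 + rnorm(n)
    normalizePanel(scorePanel(cbind(a = s, b = -s)))
  }
  A <- mk(); B <- mk()
  fused <- fusePanels(list(A, B))
  expect_gte(aucOVA(fused, lab),
             max(aucOVA(A, lab), aucOVA(B, lab)) - 0.02)
})

test_that("cross-validation folds partition samples and stratify classes", {
  lab <- rep(c("a", "b", "c"), times = c(20, 15, 10))
  plan <- cvPlan(lab, 5, seed = 2)
  expect_equal(sort(unique(plan$fold)), 1:5)
  expect_length(plan$fold, 45L)
  for (f in 1:5) {
    trainLab <- lab[plan$fold != f]
    expect_setequal(unique(trainLab), c("a", "b", "c"))
  }
  # deterministic given the seed
  expect_identical(plan$fold, cvPlan(lab, 5, seed = 2)$fold)
})
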