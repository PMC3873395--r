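test_that("log quantization maps count endpoints correctly", {
  ct <- matrix(0L, 16, 16)
  m0 <- new("CooccurrenceMatrix", counts = ct, d = 1L, theta = 0,
            sourceDims = c(4L, 4L), full = TRUE)
  expect_true(all(pixels(quantizeGLCM(m0)) == 0L))

  ct[3, 5] <- 50L
  m1 <- new("CooccurrenceMatrix", counts = ct, d = 1L, theta = 0,
            sourceDims = c(4L, 4L), full = TRUE)
  q <- pixels(quantizeGLCM(m1, 16L))
  expect_equal(q[3, 5], 15L)           # the max count hits the top level
  expect_equal(sum(q), 15L)            # everything else stays 0

  ct[7, 7] <- 50L
  m2 <- new("CooccurrenceMatrix", counts = ct, d = 1L, theta = 0,
            sourceDims = c(4L, 4L), full = TRUE)
  expect_setequal(unique(as.vector(pixels(quantizeGLCM(m2, 16L)))), c(0L, 15L))

  expect_error(quantizeGLCM(m1, 1L), "nLevels")
})

test_that("run extraction matches hand counts on simple patterns", {
  # constant image: one run per row of full width
  cimg <- grayImage(matrix(5L, 4, 6), nLevels = 16L)
  P <- runLengthMatrix(cimg, 0)
  expect_equal(P@p[6, 6], 4L)
  expect_equal(P@nRuns, 4L)

  # no two adjacent pixels equal along rows: every run has length 1
  alt <- grayImage(matrix(rep(c(0L, 1L), 18), 6, 6, byrow = TRUE), nLevels = 2L)
  P <- runLengthMatrix(alt, 0)
  expect_equal(P@nRuns, P@nPixels)
  expect_true(all(P@p[, -1] == 0L))
})

test_that("run-length matrices match the scan-and-count oracle everywhere", {
  for (seed in 1:8) {
    img <- randomGrayImage(12, 12, 4L, seed = seed)
    for (tg in c(0, 45, 90, 135)) {
      P <- runLengthMatrix(img, tg)
      expect_identical(P@p, naiveRunLength(img, tg),
                       info = sprintf("seed %d theta_GL %g", seed, tg))
      # pixel conservation: every pixel belongs to exactly one run
      expect_equal(sum(P@p %*% seq_len(ncol(P@p))), P@nPixels)
    }
  }
})

test_that("indicator formulas match the literal oracle and closed forms", {
  for (seed in 1:8) {
    img <- randomGrayImage(10, 14, 6L, seed = 100 + seed)
    for (tg in c(0, 45, 90, 135)) {
      P <- runLengthMatrix(img, tg)
      got <- rlIndicators(P)
      want <- naiveRlIndicators(P@p, P@nPixels)
      expect_equal(got, want, tolerance = 1e-10)
      expect_true(got["SRE"] * got["LRE"] >= 1 - 1e-12)  # Cauchy-Schwarz
      expect_true(got["SRE"] > 0 && got["SRE"] <= 1)
      expect_true(got["RP"] > 0 && got["RP"] <= 1)
    }
  }

  # constant rows: every run has length 5, so LRE = 25 and RP = 1/5
  img <- grayImage(matrix(2L, 3, 5), nLevels = 4L)
  v <- rlIndicators(runLengthMatrix(img, 0))
  expect_equal(unname(v["LRE"]), 25)
  expect_equal(unname(v["RP"]), 1 / 5)

  # all runs length 1
  alt <- grayImage(matrix(rep(c(0L, 1L), 8), 4, 4, byrow = TRUE), nLevels = 2L)
  v <- rlIndicators(runLengthMatrix(alt, 0))
  expect_equal(unname(v[c("SRE", "LRE", "RP")]), c(1, 1, 1))
})

test_that("the GL descriptor concatenates 352 values deterministically", {
  img <- randomGrayImage(24, 24, 256L, seed = 21)
  s <- glcmSet(img)
  v <- glDescriptor(s)
  expect_length(v, 352L)
  expect_identical(v, glDescriptor(s))

  # the symmetric co-occurrence matrix makes row and column runs coincide,
  # but axis and diagonal run directions still differ on anisotropic input
  sv <- makeImage(textureSpec(1, "stripes", size = c(16, 16), period = 4L,
                              orientation = "v"))
  vv <- glDescriptor(glcmSet(sv))
  b0 <- vv[grepl("^gl_d1_t0_r0_", names(vv))]
  b90 <- vv[grepl("^gl_d1_t0_r90_", names(vv))]
  b45 <- vv[grepl("^gl_d1_t0_r45_", names(vv))]
  expect_equal(unname(b0), unname(b90))   # symmetry of the matrix
  expect_false(isTRUE(all.equal(unname(b0), unname(b45))))
})
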