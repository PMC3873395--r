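test_that("level slices nest and empty out above the maximum count", {
  set.seed(31)
  ct <- matrix(rpois(64 * 64, 4), 64, 64)
  m <- new("CooccurrenceMatrix", counts = ct, d = 1L, theta = 0,
           sourceDims = c(64L, 64L), full = TRUE)
  slices <- levelSlices(m)
  expect_length(slices, 10L)
  for (k in 2:10) {
    expect_true(all(slices[[k]]$mask <= slices[[k - 1]]$mask))   # nesting
    expect_lte(slices[[k]]$area, slices[[k - 1]]$area)
  }

  # max count <= 1: every slice is empty (strict inequality counts > h)
  m1 <- new("CooccurrenceMatrix", counts = matrix(1L, 8, 8), d = 1L,
            theta = 0, sourceDims = c(8L, 8L), full = TRUE)
  for (s in levelSlices(m1)) expect_equal(s$area, 0L)
})

test_that("moment ellipse fitting recovers discs, rectangles and points", {
  # single pixel: degenerate fit
  f <- fitEllipse(cbind(5L, 7L))
  expect_equal(f$majorAxis, 0)
  expect_equal(f$area, 1L)

  # filled disc of radius R: both axes close to the diameter
  R <- 20
  g <- expand.grid(r = -R:R, c = -R:R)
  disc <- as.matrix(g[g$r^2 + g$c^2 <= R^2, ]) + 50L
  f <- fitEllipse(disc)
  expect_lt(abs(f$majorAxis - 2 * R) / (2 * R), 0.03)
  expect_lt(abs(f$minorAxis - 2 * R) / (2 * R), 0.03)
  expect_lt(f$eccentricity, 0.1)

  # 40 x 10 axis-aligned rectangle: orientation along rows, axis ratio ~4
  rect <- as.matrix(expand.grid(r = 1:40, c = 1:10))
  f <- fitEllipse(rect)
  expect_lt(abs(f$orientation), 0.01)       # long axis is the row axis
  expect_lt(abs(f$majorAxis / f$minorAxis - 4), 0.2)

  # empty blob: sentinel
  f0 <- fitEllipse(matrix(integer(0), 0, 2))
  expect_true(f0$empty)
})

test_that("level-set ellipses of Gaussian bumps are recovered within 5%", {
  set.seed(42)
  for (rep in 1:5) {
    S <- randomAnisoCov(sdMajor = runif(1, 22, 30), ratio = 2)
    amp <- sample(60:200, 1)
    m <- makeGaussianBumpMatrix(c(128, 128), S, amp)
    analytic <- attr(m, "levelEllipse")
    slices <- levelSlices(m)
    nchecked <- 0L
    for (s in slices) {
      le <- analytic(s$height)
      if (is.null(le)) { expect_equal(s$area, 0L); next }
      f <- fitEllipse(s$mainBlob)
      expect_lt(abs(f$majorAxis / f$minorAxis - le$axisRatio) / le$axisRatio,
                0.05, label = sprintf("rep %d h %g ratio error", rep, s$height))
      dAng <- abs(f$orientation - le$orientation)
      dAng <- min(dAng, pi - dAng)          # orientations are axial
      expect_lt(dAng, 5 * pi / 180,
                label = sprintf("rep %d h %g orientation error", rep, s$height))
      nchecked <- nchecked + 1L
    }
    expect_gt(nchecked, 5L)
  }
})

test_that("evolution features summarize the level-curve series sensibly", {
  m <- makeGaussianBumpMatrix(c(128, 128), diag(c(900, 400)), 120)
  slices <- levelSlices(m)
  f <- evolutionFeatures(slices)
  expect_length(f, 9L)
  expect_lt(f["area_slope"], 0)             # level-set area shrinks with h
  expect_equal(unname(f["n_nonempty"]), 10)
  expect_gte(f["area_ratio_low_high"], 1)

  # transpose symmetry: centroid-drift features match
  mt <- new("CooccurrenceMatrix", counts = t(counts(m)), d = 1L, theta = 0,
            sourceDims = c(256L, 256L), full = TRUE)
  ft <- evolutionFeatures(levelSlices(mt))
  expect_equal(unname(f["centroid_path"]), unname(ft["centroid_path"]),
               tolerance = 1e-10)
  expect_equal(unname(f["area_slope"]), unname(ft["area_slope"]),
               tolerance = 1e-10)

  # bit-exact reproducibility
  expect_identical(as.numeric(f), as.numeric(evolutionFeatures(levelSlices(m))))

  # all-empty series: zero vector with the empty flag
  m0 <- new("CooccurrenceMatrix", counts = matrix(0L, 16, 16), d = 1L,
            theta = 0, sourceDims = c(4L, 4L), full = TRUE)
  f0 <- evolutionFeatures(levelSlices(m0))
  expect_true(all(f0 == 0))
  expect_true(attr(f0, "empty"))
})

test_that("the SHAPE descriptor covers 13 windows and flags empty ones", {
  img <- randomGrayImage(32, 32, 256L, seed = 51)
  s <- glcmSet(img)
  sh <- shDescriptor(s)
  expect_length(sh, 13L)
  expect_equal(names(sh)[1], "whole")
  expect_length(sh[["whole"]], 72L)
  expect_length(shapeWindows(), 12L)

  # whole-window vector equals the direct evolution computation
  direct <- unlist(lapply(names(glcmMatrices(s)), function(nm) {
    fv <- evolutionFeatures(levelSlices(glcmMatrices(s)[[nm]]))
    setNames(as.numeric(fv), sprintf("sh_%s_%s", nm, shapeFeatureNames))
  }))
  expect_equal(sh[["whole"]], direct)

  # mass confined to bins (0,0)-(95,95): windows #10 and #11 see nothing
  bump <- makeGaussianBumpMatrix(c(48, 48), diag(c(100, 100)), 80)
  sconf <- s
  sconf@matrices <- lapply(s@matrices, function(x) bump)
  shc <- shDescriptor(sconf)
  expect_true(all(shc[["w10"]] == 0))
  expect_true(all(shc[["w11"]] == 0))
  expect_false(all(shc[["w5"]] == 0))       # (0,0)-(95,95) sees the bump
})
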