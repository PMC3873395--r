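# Independent brute-force oracles used to validate the vectorized
# implementations. These are deliberately written as literal loops over the
# defining formulas and share no code with the package internals.

randomGrayImage <- function(h, w, nLevels = 8L, seed = 1L) {
  set.seed(seed)
  grayImage(matrix(sample.int(nLevels, h * w, replace = TRUE) - 1L, h, w),
            nLevels = nLevels)
}

# Naive pair enumeration: double loop over all pixels, symmetric counting.
naiveGLCM <- function(img, d, theta) {
  px <- pixels(img)
  n <- nLevels(img)
  off <- switch(as.character(theta),
                "0" = c(0, d), "45" = c(-d, d), "90" = c(-d, 0),
                "135" = c(-d, -d))
  ct <- matrix(0L, n, n)
  for (r in seq_len(nrow(px))) for (c in seq_len(ncol(px))) {
    r2 <- r + off[1]; c2 <- c + off[2]
    if (r2 >= 1 && r2 <= nrow(px) && c2 >= 1 && c2 <= ncol(px)) {
      a <- px[r, c] + 1L; b <- px[r2, c2] + 1L
      ct[a, b] <- ct[a, b] + 1L
      ct[b, a] <- ct[b, a] + 1L
    }
  }
  ct
}

# Literal transcription of the 13 Haralick statistics (base-2 logs,
# 0 log 0 := 0), summing cell by cell.
naiveHaralick <- function(ct) {
  p <- ct / sum(ct)
  n1 <- nrow(p); n2 <- ncol(p)
  lg <- function(x) if (x > 0) log2(x) else 0
  px <- rowSums(p); py <- colSums(p)
  energy <- 0; entropy <- 0; inertia <- 0; idm <- 0; corrNum <- 0
  psum <- numeric(n1 + n2 - 1)          # index k+1 for k = i+j, 0-based
  pdiff <- numeric(max(n1, n2))         # index k+1 for k = |i-j|
  for (i in 0:(n1 - 1)) for (j in 0:(n2 - 1)) {
    v <- p[i + 1, j + 1]
    energy <- energy + v^2
    entropy <- entropy - v * lg(v)
    inertia <- inertia + (i - j)^2 * v
    idm <- idm + v / (1 + (i - j)^2)
    corrNum <- corrNum + i * j * v
    psum[i + j + 1] <- psum[i + j + 1] + v
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + v
  }
  mux <- sum((0:(n1 - 1)) * px); muy <- sum((0:(n2 - 1)) * py)
  sdx <- sqrt(sum(((0:(n1 - 1)) - mux)^2 * px))
  sdy <- sqrt(sum(((0:(n2 - 1)) - muy)^2 * py))
  correlation <- if (sdx * sdy == 0) 0 else (corrNum - mux * muy) / (sdx * sdy)
  ks <- 0:(n1 + n2 - 2)
  sumAverage <- sum(ks * psum)
  sumVariance <- sum((ks - sumAverage)^2 * psum)
  sumEntropy <- -sum(sapply(psum, function(v) v * lg(v)))
  kd <- 0:(max(n1, n2) - 1)
  diffAverage <- sum(kd * pdiff)
  diffVariance <- sum((kd - diffAverage)^2 * pdiff)
  diffEntropy <- -sum(sapply(pdiff, function(v) v * lg(v)))
  hx <- -sum(sapply(px, function(v) v * lg(v)))
  hy <- -sum(sapply(py, function(v) v * lg(v)))
  hxy1 <- 0; hxy2 <- 0
  for (i in seq_len(n1)) for (j in seq_len(n2)) {
    m <- px[i] * py[j]
    if (p[i, j] > 0) hxy1 <- hxy1 - p[i, j] * lg(m)
    hxy2 <- hxy2 - m * lg(m)
  }
  imc1 <- if (max(hx, hy) == 0) 0 else (entropy - hxy1) / max(hx, hy)
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - entropy))))
  c(energy = energy, correlation = correlation, inertia = inertia,
    entropy = entropy, idm = idm, sum_average = sumAverage,
    sum_variance = sumVariance, sum_entropy = sumEntropy,
    diff_average = diffAverage, diff_variance = diffVariance,
    diff_entropy = diffEntropy, imc1 = imc1, imc2 = imc2)
}

# Scan-and-count run enumeration: collects each scan line explicitly and
# walks it pixel by pixel.
naiveRunLength <- function(img, thetaGL) {
  px <- pixels(img)
  h <- nrow(px); w <- ncol(px)
  lines <- list()
  if (thetaGL == 0) {
    for (r in seq_len(h)) lines[[length(lines) + 1]] <- px[r, ]
  } else if (thetaGL == 90) {
    for (c in seq_len(w)) lines[[length(lines) + 1]] <- px[, c]
  } else if (thetaGL == 45) {
    for (s in 2:(h + w)) {     # constant r + c, walk up-right
      rs <- min(h, s - 1):max(1, s - w)
      lines[[length(lines) + 1]] <- sapply(rs, function(r) px[r, s - r])
    }
  } else if (thetaGL == 135) {
    for (dlt in (1 - w):(h - 1)) {   # constant r - c, walk down-right
      rs <- max(1, dlt + 1):min(h, w + dlt)
      lines[[length(lines) + 1]] <- sapply(rs, function(r) px[r, r - dlt])
    }
  }
  maxLen <- max(h, w)
  p <- matrix(0L, nLevels(img), maxLen)
  for (ln in lines) {
    k <- 1
    while (k <= length(ln)) {
      j <- k
      while (j < length(ln) && ln[j + 1] == ln[k]) j <- j + 1
      p[ln[k] + 1L, j - k + 1L] <- p[ln[k] + 1L, j - k + 1L] + 1L
      k <- j + 1
    }
  }
  p
}

# Literal formulas for the 11 run-length indicators (levels weighted i+1).
naiveRlIndicators <- function(p, nPixels) {
  nr <- sum(p)
  acc <- setNames(numeric(11), cooctex::rlNames)
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    v <- p[i, j]
    if (v == 0) next
    acc["SRE"] <- acc["SRE"] + v / j^2
    acc["LRE"] <- acc["LRE"] + v * j^2
    acc["LGRE"] <- acc["LGRE"] + v / i^2
    acc["HGRE"] <- acc["HGRE"] + v * i^2
    acc["SRLGE"] <- acc["SRLGE"] + v / (i^2 * j^2)
    acc["SRHGE"] <- acc["SRHGE"] + v * i^2 / j^2
    acc["LRLGE"] <- acc["LRLGE"] + v * j^2 / i^2
    acc["LRHGE"] <- acc["LRHGE"] + v * i^2 * j^2
  }
  acc["GLN"] <- sum(rowSums(p)^2)
  acc["RLN"] <- sum(colSums(p)^2)
  acc <- acc / nr
  acc["RP"] <- nr / nPixels
  acc
}

# Concordant-pair AUC, one class against the rest, averaged.
naiveAucOVA <- function(scores, labels) {
  labels <- factor(labels)
  cls <- colnames(scores)
  if (is.null(cls)) cls <- levels(labels)
  aucs <- c()
  for (k in seq_along(cls)) {
    pos <- which(labels == cls[k]); neg <- which(labels != cls[k])
    if (length(pos) == 0 || length(neg) == 0) next
    s <- 0
    for (i in pos) for (j in neg) {
      s <- s + if (scores[i, k] > scores[j, k]) 1
               else if (scores[i, k] == scores[j, k]) 0.5 else 0
    }
    aucs <- c(aucs, s / (length(pos) * length(neg)))
  }
  mean(aucs)
}

# Random anisotropic covariance with a prescribed axis-variance ratio.
randomAnisoCov <- function(sdMajor, ratio = 2, angle = NULL) {
  if (is.null(angle)) angle <- runif(1, -pi / 2, pi / 2)
  R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2, 2)
  R %*% diag(c(sdMajor^2, (sdMajor / ratio)^2)) %*% t(R)
}
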