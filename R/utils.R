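# Internal numeric helpers shared across descriptor modules.

# Sampled 2D Gaussian kernel of odd size k, normalized to unit sum.
gaussianKernel <- function(k, sigma = 1) {
  stopifnot(k >= 1, k %% 2 == 1, sigma > 0)
  r <- (k - 1) / 2
  g1 <- exp(-((-r:r)^2) / (2 * sigma^2))
  kern <- outer(g1, g1)
  kern / sum(kern)
}

# log2 with the 0 * log 0 := 0 convention, applied elementwise to x * log2(x).
xlog2x <- function(x) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- x[pos] * log2(x[pos])
  out
}

# Population (1/n) column z-scoring; constant columns map to zero.
zscoreColumns <- function(m, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(m)
  out <- sweep(m, 2, center)
  if (is.null(scale)) scale <- sqrt(colMeans(out^2))
  scale[scale < 1e-12] <- Inf   # constant column -> zeros
  sweep(out, 2, scale, "/")
}

# Connected components of a logical mask under 8-connectivity.
# EBImage::bwlabel is 4-connected; labels that touch diagonally are merged
# with a union-find pass over the label adjacency.
label8 <- function(mask) {
  storage.mode(mask) <- "integer"
  lab <- EBImage::imageData(EBImage::bwlabel(mask))
  nl <- max(lab)
  if (nl <= 1L) return(lab)
  # pairs of distinct labels that touch diagonally
  h <- nrow(lab); w <- ncol(lab)
  a1 <- lab[-h, -w]; b1 <- lab[-1, -1]    # down-right neighbor
  a2 <- lab[-h, -1]; b2 <- lab[-1, -w]    # down-left neighbor
  keep1 <- a1 > 0 & b1 > 0 & a1 != b1
  keep2 <- a2 > 0 & b2 > 0 & a2 != b2
  pairs <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(pairs) == 0L) return(lab)
  parent <- seq_len(nl)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (r in seq_len(nrow(pairs))) {
    ra <- find(pairs[r, 1]); rb <- find(pairs[r, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_len(nl), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Stratified fold assignment: within each class, samples are dealt to folds
# in a seeded random order so folds partition the data and class balance is
# preserved as far as divisibility allows.
stratifiedFolds <- function(labels, nFolds, seed) {
  labels <- as.factor(labels)
  fold <- integer(length(labels))
  rng <- local({
    set.seed(seed)
    lapply(levels(labels), function(cl) sample(which(labels == cl)))
  })
  for (idx in rng) fold[idx] <- rep_len(seq_len(nFolds), length(idx))
  fold
}
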