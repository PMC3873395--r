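#' Convert a raster to a quantized grayscale image
#'
#' Collapses RGB to luminance (weights 0.299/0.587/0.114), rescales the value
#' range linearly to `[0, nLevels - 1]` and rounds to integer levels. The
#' rescaling denominator is the full range of the inferred bit depth, not the
#' observed maximum, so an 8-bit image already coded 0..255 passes through
#' unchanged and a 16-bit image maps 65535 to 255.
#'
#' @param image a numeric matrix (grayscale) or 3D array with the third
#'   dimension holding 1 or 3 channels. Values in `[0, 1]` are treated as
#'   unit-range (the convention of EBImage readers); values up to 255 as
#'   8-bit; larger values as 16-bit.
#' @param nLevels number of quantized gray levels (default 256).
#' @return a [GrayImage-class].
#' @examples
#' img <- toGray(matrix(0:255, 16, 16))
#' nLevels(img)
#' @export
toGray <- function(image, nLevels = 256L) {
  nLevels <- as.integer(nLevels)
  if (is(image, "Image")) image <- EBImage::imageData(image)
  if (is.null(dim(image)) || length(image) == 0L)
    stop("empty image")
  if (length(dim(image)) == 3L) {
    nc <- dim(image)[3]
    if (nc == 3L) {
      image <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
    } else if (nc == 1L) {
      image <- image[, , 1]
    } else stop("unsupported channel count: ", nc)
  }
  if (!is.matrix(image)) stop("image must be 2D after channel collapse")
  if (nrow(image) < 2L || ncol(image) < 2L)
    stop("image must be at least 2x2")
  if (anyNA(image)) stop("image contains NA")
  mx <- max(image)
  maxval <- if (mx <= 1) 1 else if (mx <= 255) 255 else 65535
  q <- round(image * (nLevels - 1) / maxval)
  q[q < 0] <- 0; q[q > nLevels - 1] <- nLevels - 1
  storage.mode(q) <- "integer"
  new("GrayImage", pixels = q, nLevels = nLevels)
}

#' Construct a GrayImage from an integer matrix already on the target levels
#'
#' @param pixels integer matrix with values in `[0, nLevels - 1]`.
#' @param nLevels number of gray levels.
#' @return a [GrayImage-class].
#' @export
grayImage <- function(pixels, nLevels = 256L) {
  storage.mode(pixels) <- "integer"
  new("GrayImage", pixels = pixels, nLevels = as.integer(nLevels))
}

#' Read an image file as a quantized grayscale image
#'
#' PNG and TIFF (8/16-bit) go through EBImage; uncompressed 8-bit paletted
#' and 24-bit BMP files are parsed directly.
#'
#' @param path image file path.
#' @param nLevels number of quantized gray levels.
#' @return a [GrayImage-class].
#' @export
readGrayImage <- function(path, nLevels = 256L) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "bmp") {
    m <- readBMP(path)
    return(toGray(m, nLevels))
  }
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  # EBImage stores x (columns) in the first dimension; transpose to rows x cols
  d <- if (length(dim(d)) == 3L) aperm(d, c(2, 1, 3)) else t(d)
  toGray(d, nLevels)
}

# Minimal reader for uncompressed BMP (BITMAPINFOHEADER, 8-bit paletted or
# 24-bit BGR). Returns a matrix/array scaled like an 8-bit raster.
readBMP <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  sig <- readBin(con, "raw", 2)
  if (!identical(rawToChar(sig), "BM")) stop("not a BMP file: ", path)
  readBin(con, "integer", 2, size = 4)          # file size, reserved
  dataOffset <- readBin(con, "integer", 1, size = 4)
  headerSize <- readBin(con, "integer", 1, size = 4)
  if (headerSize < 40) stop("unsupported BMP header")
  w <- readBin(con, "integer", 1, size = 4)
  h <- readBin(con, "integer", 1, size = 4)
  readBin(con, "integer", 1, size = 2)          # planes
  bpp <- readBin(con, "integer", 1, size = 2)
  comp <- readBin(con, "integer", 1, size = 4)
  if (comp != 0) stop("compressed BMP not supported")
  if (!bpp %in% c(8L, 24L)) stop("only 8-bit and 24-bit BMP supported")
  flip <- h > 0
  h <- abs(h)
  pal <- NULL
  if (bpp == 8L) {
    seek(con, 14 + headerSize)
    palRaw <- readBin(con, "raw", 4 * 256)
    pal <- matrix(as.integer(palRaw), ncol = 4, byrow = TRUE)[, 1:3]  # B G R
  }
  seek(con, dataOffset)
  bytesPerRow <- ((bpp / 8 * w + 3) %/% 4) * 4
  raw <- readBin(con, "raw", bytesPerRow * h)
  rows <- matrix(as.integer(raw), nrow = bytesPerRow)[, seq_len(h), drop = FALSE]
  if (bpp == 8L) {
    idx <- rows[seq_len(w), , drop = FALSE] + 1L
    gray <- matrix(0.299 * pal[idx, 3] + 0.587 * pal[idx, 2] + 0.114 * pal[idx, 1],
                   nrow = w)
    out <- t(gray)
  } else {
    b <- rows[seq(1, 3 * w, 3), , drop = FALSE]
    g <- rows[seq(2, 3 * w, 3), , drop = FALSE]
    r <- rows[seq(3, 3 * w, 3), , drop = FALSE]
    out <- array(0, dim = c(h, w, 3))
    out[, , 1] <- t(r); out[, , 2] <- t(g); out[, , 3] <- t(b)
  }
  # BMP rows are stored bottom-up when height is positive
  if (flip) {
    if (length(dim(out)) == 3L) out <- out[rev(seq_len(h)), , , drop = FALSE]
    else out <- out[rev(seq_len(h)), , drop = FALSE]
  }
  out
}

#' Gaussian multi-scale stack
#'
#' Smooths the image with 2D symmetric Gaussian lowpass filters of size
#' `k = 3` and `k = 5` (standard deviation 1), giving the stack
#' `[original, smoothed_k3, smoothed_k5]`. Borders are handled by edge
#' replication and the filtered images are re-quantized to integer levels so
#' every member is a valid histogram source for the co-occurrence matrix.
#'
#' @param img a [GrayImage-class].
#' @param kernelSizes odd filter sizes (default `c(3, 5)`).
#' @param sigma Gaussian standard deviation (default 1).
#' @return list of [GrayImage-class] objects: the original followed by one
#'   smoothed image per kernel size.
#' @examples
#' img <- grayImage(matrix(sample(0:255, 64, TRUE), 8, 8))
#' stack <- gaussianStack(img)
#' length(stack)  # 3
#' @export
gaussianStack <- function(img, kernelSizes = c(3L, 5L), sigma = 1) {
  stopifnot(is(img, "GrayImage"))
  px <- img@pixels
  out <- list(original = img)
  for (k in kernelSizes) {
    kern <- gaussianKernel(k, sigma)
    sm <- EBImage::filter2(px, kern, boundary = "replicate")
    sm <- round(sm)
    sm[sm < 0] <- 0
    sm[sm > img@nLevels - 1L] <- img@nLevels - 1L
    storage.mode(sm) <- "integer"
    out[[paste0("k", k)]] <- new("GrayImage", pixels = sm, nLevels = img@nLevels)
  }
  out
}
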