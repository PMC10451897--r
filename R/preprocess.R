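## Preprocessing chain for colour fundus photographs: crop away the black
## camera border, contrast-limited adaptive histogram equalization on the
## luminance channel, Gaussian background subtraction, and minority-class
## balancing augmentation.

#' Remove redundant black borders
#'
#' Crops the image to the minimal axis-aligned bounding box containing
#' every pixel whose maximum channel intensity exceeds \code{threshold}.
#' Fundus photographs carry an uninformative black frame around the
#' circular retina; this recovers the informative region.  The operation is
#' idempotent.
#'
#' @param img image array (height x width x 3, values in [0, 255]).
#' @param threshold background intensity threshold; pixels whose max
#'   channel is \code{<= threshold} count as background (default 10).
#' @return the cropped image array.
#' @export
removeBorders <- function(img, threshold = 10) {
  assertRawImage(img)
  fg <- maxChannel(img) > threshold
  rows <- which(rowSums(fg) > 0L)
  cols <- which(colSums(fg) > 0L)
  if (length(rows) == 0L || length(cols) == 0L)
    stop("unusable image: no pixel above the background threshold")
  img[min(rows):max(rows), min(cols):max(cols), , drop = FALSE]
}

## full-range BT.601 luma/chroma split used for colour-preserving CLAHE
rgbToYCbCr <- function(img) {
  y  <- 0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
  cb <- 128 + (img[, , 3] - y) * 0.564
  cr <- 128 + (img[, , 1] - y) * 0.713
  list(y = y, cb = cb, cr = cr)
}

yCbCrToRgb <- function(y, cb, cr) {
  r <- y + 1.403 * (cr - 128)
  b <- y + 1.773 * (cb - 128)
  g <- (y - 0.299 * r - 0.114 * b) / 0.587
  out <- array(0, c(dim(y), 3L))
  out[, , 1] <- r; out[, , 2] <- g; out[, , 3] <- b
  clip255(out)
}

## per-tile clipped-histogram lookup table.  clipLimit follows the OpenCV
## convention: the clip ceiling is clipLimit times the uniform bin height,
## clipped excess is redistributed uniformly, and the mapping is
## lut(v) = round(cdf(v) * 255 / n).
claheTileLut <- function(values, clipLimit) {
  n <- length(values)
  tab <- tabulate(values + 1L, nbins = 256L)
  ceilingCount <- max(1, clipLimit * n / 256)
  excess <- sum(pmax(tab - ceilingCount, 0))
  tab <- pmin(tab, ceilingCount) + excess / 256
  round(cumsum(tab) * 255 / n)
}

#' Contrast-limited adaptive histogram equalization
#'
#' Applies CLAHE to the luminance channel of a luma/chroma decomposition
#' and recombines with the untouched chroma.  The image is divided into a
#' \code{tileGrid x tileGrid} grid; each tile's 256-bin histogram is
#' clipped at \code{clipLimit} times the uniform bin height, the excess is
#' redistributed uniformly, and per-tile equalization mappings are blended
#' bilinearly between neighbouring tile centres.
#'
#' @param img image array.
#' @param clipLimit contrast clip limit (default 7).
#' @param tileGrid number of tiles per axis (default 6).
#' @return enhanced image array, same shape, values in [0, 255].
#' @export
claheEnhance <- function(img, clipLimit = 7, tileGrid = 6L) {
  assertRawImage(img)
  if (!is.finite(clipLimit) || clipLimit <= 0) stop("clipLimit must be > 0")
  tileGrid <- as.integer(tileGrid)
  h <- dim(img)[1]; w <- dim(img)[2]
  if (tileGrid < 1L) stop("tileGrid must be >= 1")
  if (tileGrid > h || tileGrid > w)
    stop("tile grid finer than the image: each tile must hold at least one pixel")

  ycc <- rgbToYCbCr(img)
  v <- matrix(as.integer(pmin(pmax(round(ycc$y), 0), 255)), h, w)

  rowB <- round(seq(0L, h, length.out = tileGrid + 1L))
  colB <- round(seq(0L, w, length.out = tileGrid + 1L))
  luts <- array(0, c(tileGrid, tileGrid, 256L))
  for (i in seq_len(tileGrid)) for (j in seq_len(tileGrid)) {
    tile <- v[(rowB[i] + 1L):rowB[i + 1L], (colB[j] + 1L):colB[j + 1L]]
    luts[i, j, ] <- claheTileLut(as.integer(tile), clipLimit)
  }

  ## bilinear blend between tile centres, clamped at the image border
  blend <- function(coord, bounds) {
    centers <- (bounds[-length(bounds)] + bounds[-1] + 1) / 2
    lo <- findInterval(coord, centers)
    lo <- pmin(pmax(lo, 1L), length(centers) - 1L)
    if (length(centers) == 1L) return(list(lo = rep(1L, length(coord)),
                                           hi = rep(1L, length(coord)),
                                           w = rep(0, length(coord))))
    wgt <- (coord - centers[lo]) / (centers[lo + 1L] - centers[lo])
    list(lo = lo, hi = lo + 1L, w = pmin(pmax(wgt, 0), 1))
  }
  rb <- blend(seq_len(h), rowB)
  cb <- blend(seq_len(w), colB)

  ri0 <- matrix(rb$lo, h, w); ri1 <- matrix(rb$hi, h, w)
  rw  <- matrix(rb$w,  h, w)
  ci0 <- matrix(cb$lo, h, w, byrow = TRUE); ci1 <- matrix(cb$hi, h, w, byrow = TRUE)
  cw  <- matrix(cb$w,  h, w, byrow = TRUE)
  vv <- as.vector(v) + 1L
  yOut <- (1 - rw) * (1 - cw) * matrix(luts[cbind(as.vector(ri0), as.vector(ci0), vv)], h, w) +
          (1 - rw) * cw       * matrix(luts[cbind(as.vector(ri0), as.vector(ci1), vv)], h, w) +
          rw       * (1 - cw) * matrix(luts[cbind(as.vector(ri1), as.vector(ci0), vv)], h, w) +
          rw       * cw       * matrix(luts[cbind(as.vector(ri1), as.vector(ci1), vv)], h, w)

  yCbCrToRgb(yOut, ycc$cb, ycc$cr)
}

## truncated sampled Gaussian kernel, radius ceil(3*sigma) (capped so the
## kernel fits in the image), normalized to sum 1
gaussianKernel2d <- function(sigma, maxRadius) {
  radius <- max(1L, min(as.integer(ceiling(3 * sigma)), maxRadius))
  d <- (-radius):radius
  w1 <- exp(-d^2 / (2 * sigma^2))
  k <- outer(w1, w1)
  k / sum(k)
}

#' Gaussian background-subtraction enhancement
#'
#' Computes \code{clip(kappa * (x - blur(x, sigma)) + delta, 0, 255)}
#' per channel, where \code{blur} is convolution with a truncated sampled
#' Gaussian (radius \code{ceil(3*sigma)}, replicated borders).  Subtracting
#' the local weighted average flattens uneven illumination so vessel-scale
#' structure stands out around the mid-grey offset \code{delta}.
#'
#' @param img image array.
#' @param kappa gain (default 4).
#' @param sigma blur standard deviation in pixels; the preprocessing chain
#'   derives it as image width / \code{sigmaDivisor}.
#' @param delta intensity offset (default 128).
#' @return enhanced image array.
#' @export
gaussianEnhance <- function(img, kappa = 4, sigma, delta = 128) {
  assertRawImage(img)
  if (!is.finite(kappa) || !is.finite(sigma) || !is.finite(delta))
    stop("kappa, sigma and delta must be finite")
  if (sigma <= 0) stop("sigma must be > 0")
  h <- dim(img)[1]; w <- dim(img)[2]
  k <- gaussianKernel2d(sigma, maxRadius = max(1L, (min(h, w) - 1L) %/% 2L))
  eb <- rawToEBImage(img)
  blurred <- ebImageToRaw(EBImage::filter2(eb, k, boundary = "replicate"))
  clip255(kappa * (img - blurred) + delta)
}

#' Full preprocessing chain
#'
#' Border removal, then CLAHE, then Gaussian background subtraction, with
#' the blur scale tied to the post-crop width
#' (\code{sigma = width / sigmaDivisor}).
#'
#' @param img image array.
#' @param config a \code{\link{PreprocessConfig}}.
#' @return preprocessed image array.
#' @export
preprocessImage <- function(img, config = PreprocessConfig()) {
  stopifnot(is(config, "PreprocessConfig"))
  img <- removeBorders(img, config@backgroundThreshold)
  img <- claheEnhance(img, config@clipLimit, config@tileGrid)
  gaussianEnhance(img, config@kappa, dim(img)[2] / config@sigmaDivisor,
                  config@delta)
}

## ---------------------------------------------------------------------------
## Minority-class balancing augmentation
## ---------------------------------------------------------------------------

augmentOps <- c("rotate", "hflip", "vflip", "scale", "shiftH", "shiftV",
                "shear")

## one random geometric transform pipeline; vacated pixels are filled with
## black, matching the photograph's background
applyAugmentation <- function(img, ops, ranges) {
  h <- dim(img)[1]; w <- dim(img)[2]
  x <- rawToEBImage(img)
  for (op in ops) {
    x <- switch(op,
      rotate = EBImage::rotate(x, runif(1, -ranges$rotate, ranges$rotate),
                               output.dim = c(w, h), bg.col = 0),
      hflip = EBImage::flop(x),
      vflip = EBImage::flip(x),
      scale = {
        s <- runif(1, ranges$scale[1], ranges$scale[2])
        y <- EBImage::resize(x, w = max(4L, round(w * s)),
                             h = max(4L, round(h * s)))
        d <- dim(y)
        out <- EBImage::Image(array(0, c(w, h, 3L)),
                              colormode = EBImage::Color)
        cw <- min(w, d[1]); ch <- min(h, d[2])
        ox <- (w - cw) %/% 2L; oy <- (h - ch) %/% 2L
        sx <- (d[1] - cw) %/% 2L; sy <- (d[2] - ch) %/% 2L
        out[ox + seq_len(cw), oy + seq_len(ch), ] <-
          y[sx + seq_len(cw), sy + seq_len(ch), ]
        out
      },
      shiftH = EBImage::translate(x, c(round(runif(1, -ranges$shift, ranges$shift) * w), 0), bg.col = 0),
      shiftV = EBImage::translate(x, c(0, round(runif(1, -ranges$shift, ranges$shift) * h)), bg.col = 0),
      shear = {
        sh <- tan(runif(1, -ranges$shear, ranges$shear) * pi / 180)
        m <- matrix(c(1, sh, -sh * h / 2, 0, 1, 0), nrow = 3L, ncol = 2L)
        EBImage::affine(x, m, output.dim = c(w, h), bg.col = 0)
      },
      stop("unknown augmentation op: ", op))
  }
  clip255(ebImageToRaw(x))
}

#' Balance classes by augmenting the minority class
#'
#' Upsamples the minority class with randomly transformed copies (rotation,
#' flips, proportional scaling, shifts, shear; vacated regions filled with
#' black) until both class counts are equal.  Majority-class samples and
#' every original sample are returned unchanged.  Deterministic for a fixed
#' seed.
#'
#' @param samples list of samples, each a list with elements \code{image}
#'   (raw image array) and \code{label} (0 or 1).
#' @param seed integer seed.
#' @param opSet character vector of augmentation operations to draw from
#'   (default: all of rotate, hflip, vflip, scale, shiftH, shiftV, shear).
#' @param ranges list of parameter ranges: \code{rotate} max degrees (30),
#'   \code{shift} max fraction (0.1), \code{scale} factor range
#'   (0.9--1.1), \code{shear} max degrees (10).
#' @return list of samples with equal class counts; augmented samples carry
#'   an \code{augmented = TRUE} flag and the index of their source sample.
#' @export
augmentMinority <- function(samples, seed = 1L, opSet = augmentOps,
                            ranges = list(rotate = 30, shift = 0.1,
                                          scale = c(0.9, 1.1), shear = 10)) {
  stopifnot(length(samples) > 0L)
  opSet <- match.arg(opSet, augmentOps, several.ok = TRUE)
  labels <- vapply(samples, function(s) as.integer(s$label), integer(1))
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary (0/1)")
  counts <- table(factor(labels, levels = c(0L, 1L)))
  if (any(counts == 0L))
    stop("both classes must be present to balance them")
  if (counts[1] == counts[2]) return(samples)
  minorityLabel <- as.integer(names(counts)[which.min(counts)])
  need <- abs(diff(as.integer(counts)))
  minIdx <- which(labels == minorityLabel)

  set.seed(as.integer(seed))
  extra <- vector("list", need)
  for (k in seq_len(need)) {
    src <- minIdx[sample.int(length(minIdx), 1L)]
    nOps <- sample.int(min(3L, length(opSet)), 1L)
    ops <- sample(opSet, nOps)
    extra[[k]] <- list(image = applyAugmentation(samples[[src]]$image, ops,
                                                 ranges),
                       label = minorityLabel, augmented = TRUE,
                       source = src)
  }
  c(samples, extra)
}
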