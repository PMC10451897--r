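## Raw images are numeric arrays of dim (height, width, 3), RGB channel
## order, intensities in [0, 255].  EBImage stores (width, height, channel)
## in [0, 1]; the two helpers below are the only place that convention is
## touched.

#' @importFrom EBImage Image readImage writeImage resize filter2 rotate
#'   translate affine flip flop imageData colorMode Color
NULL

assertRawImage <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected a height x width x 3 image array")
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop("image must have at least one row and one column")
  if (anyNA(img) || min(img) < 0 || max(img) > 255)
    stop("image intensities must be finite and within [0, 255]")
  invisible(TRUE)
}

rawToEBImage <- function(img) {
  EBImage::Image(aperm(img, c(2L, 1L, 3L)) / 255, colormode = EBImage::Color)
}

ebImageToRaw <- function(x) {
  d <- EBImage::imageData(x)
  if (length(dim(d)) == 2L) d <- array(rep(d, 3L), c(dim(d), 3L))
  if (dim(d)[3] > 3L) d <- d[, , 1:3, drop = FALSE]
  out <- aperm(d, c(2L, 1L, 3L)) * 255
  out[out < 0] <- 0
  out[out > 255] <- 255
  out
}

#' Read a fundus image
#'
#' Reads a PNG or JPEG file into the package's raw-image convention:
#' a \code{height x width x 3} numeric array, RGB, values in [0, 255].
#'
#' @param path file path.
#' @return image array.
#' @export
readFundusImage <- function(path) {
  ebImageToRaw(EBImage::readImage(path))
}

#' Write a fundus image
#'
#' @param img image array (see \code{\link{readFundusImage}}).
#' @param path output path; format follows the file extension
#'   (\code{.png} or \code{.jpg}).
#' @return \code{path}, invisibly.
#' @export
writeFundusImage <- function(img, path) {
  assertRawImage(img)
  EBImage::writeImage(rawToEBImage(img), path)
  invisible(path)
}

#' Resize an image
#'
#' Bilinear resize to a square target, used to produce each branch's input.
#'
#' @param img image array.
#' @param size target side length in pixels.
#' @return resized image array of dim \code{(size, size, 3)}.
#' @export
resizeImage <- function(img, size) {
  assertRawImage(img)
  if (dim(img)[1] == size && dim(img)[2] == size) return(img)
  ebImageToRaw(EBImage::resize(rawToEBImage(img), w = size, h = size))
}

clip255 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

## max over the three channels, returned as height x width matrix
maxChannel <- function(img) {
  matrix(pmax(img[, , 1], img[, , 2], img[, , 3]),
         dim(img)[1], dim(img)[2])
}
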