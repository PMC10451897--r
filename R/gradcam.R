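## Gradient-weighted class activation mapping on the patch-token grid.
## The hook point is the chosen branch's patch-token state after the last
## cross-scale repetition (the fusion leaves patch tokens unchanged, so
## this equals the last encoder-block output); the classification token is
## excluded from the map.

#' Grad-CAM heatmap for one image
#'
#' Computes the gradient of the fused target-class probability with
#' respect to the chosen branch's patch tokens at the last cross-scale
#' repetition, averages the gradient over the token grid to obtain
#' per-channel weights, and forms the map as the ReLU of the
#' channel-weighted token features, normalized to [0, 1] and bilinearly
#' upsampled to the image size.
#'
#' @param model a \code{\link{MILCTModel-class}} object.
#' @param img raw image array.
#' @param targetClass class whose evidence is visualized (0 or 1).
#' @param branch \code{"C"} or \code{"F"}.
#' @return a heatmap: list with \code{grid} (sqrt(n) x sqrt(n) matrix in
#'   [0, 1]), \code{upsampled} (image-size matrix), \code{branch} and
#'   \code{targetClass}.
#' @export
gradCamMap <- function(model, img, targetClass = 1L, branch = c("C", "F")) {
  stopifnot(is(model, "MILCTModel"))
  branch <- match.arg(branch)
  if (!targetClass %in% c(0L, 1L)) stop("targetClass must be 0 or 1")
  fwd <- milctFwd(model, img)
  eta <- model@spec@eta
  tsel <- numeric(model@spec@nClasses)
  tsel[targetClass + 1L] <- 1

  ## d(fused prob)/d(head probs), then through each head's softmax
  dProb <- list(mlpF = eta / 2 * tsel, mlpC = eta / 2 * tsel,
                milF = (1 - eta) / 2 * tsel, milC = (1 - eta) / 2 * tsel)
  dLogits <- lapply(names(dProb), function(nm) {
    p <- fwd$probs[[nm]]
    dp <- dProb[[nm]]
    p * (dp - sum(dp * p))
  })
  names(dLogits) <- names(dProb)

  bw <- milctBwd(model, fwd, dLogits)
  hook <- if (branch == "C") fwd$cache$bb$hookC else fwd$cache$bb$hookF
  dHook <- if (branch == "C") bw$dHookC else bw$dHookF
  feats <- hook[-1L, , drop = FALSE]
  grads <- dHook[-1L, , drop = FALSE]
  n <- nrow(feats)
  g <- sqrt(n)
  if (g != round(g)) stop("patch count is not a perfect square")
  g <- as.integer(g)

  w <- colMeans(grads)
  map <- pmax(as.vector(feats %*% w), 0)
  grid <- matrix(map, g, g, byrow = TRUE)  # patch-grid row-major order
  if (max(grid) > 0) grid <- grid / max(grid)

  up <- EBImage::resize(EBImage::Image(t(grid)),
                        w = dim(img)[2], h = dim(img)[1])
  up <- t(EBImage::imageData(up))
  up[up < 0] <- 0; up[up > 1] <- 1
  list(grid = grid, upsampled = up, branch = branch,
       targetClass = as.integer(targetClass))
}

#' Overlay a heatmap on an image
#'
#' Blends a Grad-CAM map (red channel emphasis) onto the photograph for
#' qualitative inspection.
#'
#' @param img raw image array.
#' @param heatmap result of \code{\link{gradCamMap}}.
#' @param alpha blending weight of the heatmap (default 0.45).
#' @return raw image array of the overlay.
#' @export
overlayHeatmap <- function(img, heatmap, alpha = 0.45) {
  assertRawImage(img)
  hm <- heatmap$upsampled
  out <- img
  out[, , 1] <- (1 - alpha) * img[, , 1] + alpha * 255 * hm
  out[, , 2] <- (1 - alpha) * img[, , 2]
  out[, , 3] <- (1 - alpha) * img[, , 3] + alpha * 255 * (1 - hm) * 0.3
  clip255(out)
}
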