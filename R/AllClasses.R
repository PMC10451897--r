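#' @import methods
#' @importFrom stats rnorm runif qnorm pnorm dnorm var sd
#' @importFrom utils read.csv write.csv head tail
NULL

## ---------------------------------------------------------------------------
## Branch specification
## ---------------------------------------------------------------------------

#' Branch specification for one transformer branch
#'
#' A \code{BranchSpec} fixes the geometry of one branch of the cross-scale
#' backbone: the square patch size \code{p}, the square input size \code{s}
#' the image is resized to, the token embedding dimension \code{q}, the
#' number of encoder blocks run per cross-scale repetition, the number of
#' self-attention heads, and the feed-forward hidden-width expansion factor.
#' The branch produces \code{(s/p)^2} patch tokens plus one classification
#' token.
#'
#' @slot patchSize integer, side length of a square patch in pixels.
#' @slot inputSize integer, side length the image is resized to; must be a
#'   multiple of \code{patchSize}.
#' @slot embedDim integer, token dimension; must be a multiple of
#'   \code{nHeads}.
#' @slot depth integer, encoder blocks per cross-scale repetition.
#' @slot nHeads integer, self-attention heads.
#' @slot ffnExpansion integer, hidden width multiplier of the feed-forward
#'   network.
#' @export
setClass("BranchSpec",
  representation(patchSize = "integer", inputSize = "integer",
                 embedDim = "integer", depth = "integer",
                 nHeads = "integer", ffnExpansion = "integer"))

setValidity("BranchSpec", function(object) {
  msg <- character()
  if (object@patchSize < 1L) msg <- c(msg, "patchSize must be >= 1")
  if (object@inputSize %% object@patchSize != 0L)
    msg <- c(msg, "inputSize must be divisible by patchSize")
  if (object@embedDim < 1L) msg <- c(msg, "embedDim must be >= 1")
  if (object@embedDim %% object@nHeads != 0L)
    msg <- c(msg, "embedDim must be divisible by nHeads")
  if (object@depth < 0L) msg <- c(msg, "depth must be >= 0")
  if (object@ffnExpansion < 1L) msg <- c(msg, "ffnExpansion must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @describeIn BranchSpec-class Constructor.
#' @param patchSize,inputSize,embedDim,depth,nHeads,ffnExpansion see slots.
#' @export
BranchSpec <- function(patchSize, inputSize, embedDim, depth = 1L,
                       nHeads = 1L, ffnExpansion = 4L) {
  new("BranchSpec", patchSize = as.integer(patchSize),
      inputSize = as.integer(inputSize), embedDim = as.integer(embedDim),
      depth = as.integer(depth), nHeads = as.integer(nHeads),
      ffnExpansion = as.integer(ffnExpansion))
}

#' Number of patch tokens of a branch
#' @param spec a \code{BranchSpec}.
#' @return integer, \code{(inputSize/patchSize)^2}.
#' @export
numPatches <- function(spec) {
  as.integer((spec@inputSize %/% spec@patchSize)^2)
}

setMethod("show", "BranchSpec", function(object) {
  cat(sprintf(
    "BranchSpec: patch %dpx, input %dpx (%d tokens), dim %d, depth %d, %d heads, ffn x%d\n",
    object@patchSize, object@inputSize, numPatches(object),
    object@embedDim, object@depth, object@nHeads, object@ffnExpansion))
})

## ---------------------------------------------------------------------------
## Model specification
## ---------------------------------------------------------------------------

#' Full model specification
#'
#' Combines the fine-grained (F) and coarse-grained (C) branch
#' specifications with the number of cross-scale encoder repetitions
#' \code{nReps} (each repetition runs the per-branch encoder stacks followed
#' by one multi-head cross-scale attention fusion), the number of classes
#' and the loss weight \code{eta} that balances the classification-token
#' heads against the bag-level heads.
#'
#' @slot fBranch,cBranch \code{BranchSpec} for each branch.
#' @slot nReps integer, cross-scale encoder repetitions.
#' @slot nClasses integer, number of classes (2 for the light-reflex task).
#' @slot eta numeric in [0,1], loss weight of the classification-token head.
#' @export
setClass("ModelSpec",
  representation(fBranch = "BranchSpec", cBranch = "BranchSpec",
                 nReps = "integer", nClasses = "integer", eta = "numeric"))

setValidity("ModelSpec", function(object) {
  msg <- character()
  if (object@nReps < 0L) msg <- c(msg, "nReps must be >= 0")
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (object@eta < 0 || object@eta > 1) msg <- c(msg, "eta must be in [0,1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn ModelSpec-class Constructor.
#' @param fBranch,cBranch,nReps,nClasses,eta see slots.
#' @export
ModelSpec <- function(fBranch, cBranch, nReps = 3L, nClasses = 2L,
                      eta = 0.5) {
  new("ModelSpec", fBranch = fBranch, cBranch = cBranch,
      nReps = as.integer(nReps), nClasses = as.integer(nClasses),
      eta = as.numeric(eta))
}

#' Default model specification
#'
#' The reference configuration of the two-branch model: fine branch with
#' 12-px patches on 240-px inputs (400 tokens, dim 96, depth 1), coarse
#' branch with 16-px patches on 224-px inputs (196 tokens, dim 192,
#' depth 4), three cross-scale repetitions.  Head counts follow a 32-wide
#' head convention (3 and 6 heads), feed-forward expansion 4.
#'
#' @param eta loss weight of the classification-token heads (default 0.5).
#' @return a \code{ModelSpec}.
#' @export
defaultModelSpec <- function(eta = 0.5) {
  ModelSpec(
    fBranch = BranchSpec(12L, 240L, 96L, depth = 1L, nHeads = 3L),
    cBranch = BranchSpec(16L, 224L, 192L, depth = 4L, nHeads = 6L),
    nReps = 3L, eta = eta)
}

#' Desk-scale model specification
#'
#' A reduced configuration (dims 32/64, single cross-scale repetition)
#' sized for CPU training on small synthetic datasets; both branches share
#' the same input size so the raw synthetic image needs no resizing.
#'
#' @param imageSize square input size in pixels; must be divisible by 12
#'   and 16 (default 96).
#' @param eta loss weight (default 0.5).
#' @return a \code{ModelSpec}.
#' @export
tinyModelSpec <- function(imageSize = 96L, eta = 0.5) {
  ModelSpec(
    fBranch = BranchSpec(12L, imageSize, 32L, depth = 1L, nHeads = 2L),
    cBranch = BranchSpec(16L, imageSize, 64L, depth = 2L, nHeads = 4L),
    nReps = 1L, eta = eta)
}

setMethod("show", "ModelSpec", function(object) {
  cat(sprintf("ModelSpec: %d cross-scale repetition(s), %d classes, eta %.2f\n",
              object@nReps, object@nClasses, object@eta))
  cat("  F-"); show(object@fBranch)
  cat("  C-"); show(object@cBranch)
})

## ---------------------------------------------------------------------------
## MIL head specification
## ---------------------------------------------------------------------------

#' Bag-level (multiple-instance) head specification
#'
#' @slot embedDim integer, instance embedding dimension \code{m}.
#' @slot attnDim integer, hidden dimension \code{l} of the attention scorer.
#' @slot nClasses integer.
#' @export
setClass("MILHeadSpec",
  representation(embedDim = "integer", attnDim = "integer",
                 nClasses = "integer"))

setValidity("MILHeadSpec", function(object) {
  msg <- character()
  if (object@embedDim < 1L) msg <- c(msg, "embedDim must be >= 1")
  if (object@attnDim < 1L) msg <- c(msg, "attnDim must be >= 1")
  if (object@nClasses < 2L) msg <- c(msg, "nClasses must be >= 2")
  if (length(msg)) msg else TRUE
})

#' @describeIn MILHeadSpec-class Constructor.
#' @param embedDim,attnDim,nClasses see slots.
#' @export
MILHeadSpec <- function(embedDim = 128L, attnDim = 64L, nClasses = 2L) {
  new("MILHeadSpec", embedDim = as.integer(embedDim),
      attnDim = as.integer(attnDim), nClasses = as.integer(nClasses))
}

setMethod("show", "MILHeadSpec", function(object) {
  cat(sprintf("MILHeadSpec: embedding %d, attention hidden %d, %d classes\n",
              object@embedDim, object@attnDim, object@nClasses))
})

## ---------------------------------------------------------------------------
## Preprocessing configuration
## ---------------------------------------------------------------------------

#' Preprocessing configuration
#'
#' Parameters of the image preprocessing chain: border removal threshold,
#' CLAHE clip limit and tile grid, and the Gaussian background-subtraction
#' enhancement \code{clip(kappa * (x - blur(x, sigma)) + delta, 0, 255)}
#' with \code{sigma = width / sigmaDivisor}.
#'
#' @slot clipLimit numeric > 0, CLAHE contrast clipping threshold (relative
#'   to a uniform histogram, OpenCV convention).
#' @slot tileGrid integer >= 1, CLAHE tiles per image axis.
#' @slot kappa numeric, enhancement gain.
#' @slot sigmaDivisor numeric > 0, blur scale divisor; the blur standard
#'   deviation is the post-crop image width divided by this.
#' @slot delta numeric in [0,255], intensity offset.
#' @slot backgroundThreshold numeric, max-channel intensity at or below
#'   which a pixel counts as background during border removal.
#' @export
setClass("PreprocessConfig",
  representation(clipLimit = "numeric", tileGrid = "integer",
                 kappa = "numeric", sigmaDivisor = "numeric",
                 delta = "numeric", backgroundThreshold = "numeric"))

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  if (!is.finite(object@clipLimit) || object@clipLimit <= 0)
    msg <- c(msg, "clipLimit must be > 0")
  if (object@tileGrid < 1L) msg <- c(msg, "tileGrid must be >= 1")
  if (!is.finite(object@sigmaDivisor) || object@sigmaDivisor <= 0)
    msg <- c(msg, "sigmaDivisor must be > 0")
  if (object@delta < 0 || object@delta > 255)
    msg <- c(msg, "delta must be in [0,255]")
  if (length(msg)) msg else TRUE
})

#' @describeIn PreprocessConfig-class Constructor with the reference
#'   defaults (clip limit 7, 6x6 tiles, gain 4, sigma = width/30,
#'   offset 128, background threshold 10).
#' @param clipLimit,tileGrid,kappa,sigmaDivisor,delta,backgroundThreshold
#'   see slots.
#' @export
PreprocessConfig <- function(clipLimit = 7, tileGrid = 6L, kappa = 4,
                             sigmaDivisor = 30, delta = 128,
                             backgroundThreshold = 10) {
  new("PreprocessConfig", clipLimit = as.numeric(clipLimit),
      tileGrid = as.integer(tileGrid), kappa = as.numeric(kappa),
      sigmaDivisor = as.numeric(sigmaDivisor), delta = as.numeric(delta),
      backgroundThreshold = as.numeric(backgroundThreshold))
}

setMethod("show", "PreprocessConfig", function(object) {
  cat(sprintf(
    "PreprocessConfig: clipLimit %.3g, tiles %dx%d, kappa %.3g, sigma = w/%.3g, delta %.3g, bg <= %.3g\n",
    object@clipLimit, object@tileGrid, object@tileGrid, object@kappa,
    object@sigmaDivisor, object@delta, object@backgroundThreshold))
})

## ---------------------------------------------------------------------------
## Synthetic generator configuration
## ---------------------------------------------------------------------------

#' Synthetic fundus generator configuration
#'
#' Controls the deterministic two-class phantom generator: an orange-tinted
#' circular disc on black background carrying dark curvilinear vessels;
#' positive-class images additionally carry a bright central reflex stripe
#' along a subset of vessels (the arteriolar light reflex the classifier is
#' meant to detect).
#'
#' @slot imageSize integer >= 64, square image side in pixels.
#' @slot nPerClass integer >= 1, images per class for dataset generation.
#' @slot seed integer, master seed.
#' @slot nVessels integer length-2 range of vessel counts per image.
#' @slot vesselWidth numeric length-2 range of vessel widths in pixels.
#' @slot reflexWidthFraction numeric in (0,1], stripe width as fraction of
#'   the vessel width.
#' @slot reflexBrightness numeric, intensity added along the stripe.
#' @export
setClass("SynthConfig",
  representation(imageSize = "integer", nPerClass = "integer",
                 seed = "integer", nVessels = "integer",
                 vesselWidth = "numeric", reflexWidthFraction = "numeric",
                 reflexBrightness = "numeric"))

setValidity("SynthConfig", function(object) {
  msg <- character()
  if (object@imageSize < 64L) msg <- c(msg, "imageSize must be >= 64")
  if (object@nPerClass < 1L) msg <- c(msg, "nPerClass must be >= 1")
  if (length(object@nVessels) != 2L || any(object@nVessels < 1L))
    msg <- c(msg, "nVessels must be a length-2 positive range")
  if (length(object@vesselWidth) != 2L || any(object@vesselWidth <= 0))
    msg <- c(msg, "vesselWidth must be a length-2 positive range")
  if (object@reflexWidthFraction <= 0 || object@reflexWidthFraction > 1)
    msg <- c(msg, "reflexWidthFraction must be in (0,1]")
  if (length(msg)) msg else TRUE
})

#' @describeIn SynthConfig-class Constructor.
#' @param imageSize,nPerClass,seed,nVessels,vesselWidth,reflexWidthFraction,reflexBrightness
#'   see slots.
#' @export
SynthConfig <- function(imageSize = 96L, nPerClass = 100L, seed = 1L,
                        nVessels = c(6L, 10L), vesselWidth = c(2.5, 5),
                        reflexWidthFraction = 0.45, reflexBrightness = 70) {
  new("SynthConfig", imageSize = as.integer(imageSize),
      nPerClass = as.integer(nPerClass), seed = as.integer(seed),
      nVessels = as.integer(nVessels), vesselWidth = as.numeric(vesselWidth),
      reflexWidthFraction = as.numeric(reflexWidthFraction),
      reflexBrightness = as.numeric(reflexBrightness))
}

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf(
    "SynthConfig: %dpx, %d per class, seed %d, %d-%d vessels of %.1f-%.1f px, reflex %.0f%% width +%.0f\n",
    object@imageSize, object@nPerClass, object@seed, object@nVessels[1],
    object@nVessels[2], object@vesselWidth[1], object@vesselWidth[2],
    100 * object@reflexWidthFraction, object@reflexBrightness))
})

## ---------------------------------------------------------------------------
## Model container
## ---------------------------------------------------------------------------

#' Assembled model
#'
#' Holds the model and head specifications together with the parameter tree
#' (a nested list of matrices/vectors) of the backbone, the per-branch
#' classification-token heads and the per-branch bag-level heads.
#'
#' @slot spec a \code{ModelSpec}.
#' @slot milSpec a \code{MILHeadSpec}.
#' @slot params nested list of numeric arrays.
#' @export
setClass("MILCTModel",
  representation(spec = "ModelSpec", milSpec = "MILHeadSpec",
                 params = "list"))

#' Number of trainable parameters
#' @param model a \code{MILCTModel}.
#' @return integer count of all parameter entries.
#' @export
parameterCount <- function(model) {
  stopifnot(is(model, "MILCTModel"))
  paramCountTree(model@params)
}

setMethod("show", "MILCTModel", function(object) {
  cat(sprintf("MILCTModel with %s trainable parameters (%.2f M)\n",
              format(parameterCount(object), big.mark = ","),
              parameterCount(object) / 1e6))
  show(object@spec)
  show(object@milSpec)
})
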