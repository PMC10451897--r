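## Full model: cross-scale backbone, one classification-token (MLP) head
## per branch, one bag-level (MIL) head per branch, the jointly weighted
## cross-entropy objective and the inference-time fusion rule.

initMlpHeadParams <- function(q, nClasses) {
  list(ln = initLayerNorm(q),
       W = matrix(truncNormal(q * nClasses, sd = 1 / sqrt(q)), q, nClasses),
       b = numeric(nClasses))
}

#' Build the full model
#'
#' Initializes all trainable parameters (truncated normal with fan-in
#' scaled sd for weight matrices, sd 0.02 for tokens and position
#' embeddings; zeros for biases; unit scale / zero offset for layer norms) for
#' the backbone, the per-branch classification-token heads (layer norm
#' followed by a single linear map) and the per-branch bag-level heads.
#'
#' @param spec a \code{\link{ModelSpec}} (default: the reference
#'   configuration of \code{\link{defaultModelSpec}}).
#' @param milSpec a \code{\link{MILHeadSpec}}.
#' @param seed optional integer; when given, initialization is
#'   reproducible.
#' @return a \code{\link{MILCTModel-class}} object.
#' @export
buildModel <- function(spec = defaultModelSpec(), milSpec = MILHeadSpec(),
                       seed = NULL) {
  stopifnot(is(spec, "ModelSpec"), is(milSpec, "MILHeadSpec"))
  validObject(spec); validObject(milSpec)
  if (spec@nClasses != milSpec@nClasses)
    stop("spec and milSpec disagree on the number of classes")
  if (!is.null(seed)) set.seed(as.integer(seed))
  params <- list(
    backbone = initBackboneParams(spec),
    mlp = list(F = initMlpHeadParams(spec@fBranch@embedDim, spec@nClasses),
               C = initMlpHeadParams(spec@cBranch@embedDim, spec@nClasses)),
    mil = list(F = initMILBranchParams(spec@fBranch@embedDim, milSpec),
               C = initMILBranchParams(spec@cBranch@embedDim, milSpec)))
  new("MILCTModel", spec = spec, milSpec = milSpec, params = params)
}

mlpHeadFwd <- function(tokens, p) {
  ln <- lnFwd(tokens[1L, , drop = FALSE], p$ln$gamma, p$ln$beta)
  logits <- drop(linearFwd(ln$Y, p$W, p$b))
  list(logits = logits, cache = list(ln = ln, p = p))
}

mlpHeadBwd <- function(dLogits, cache) {
  g <- linearBwd(matrix(dLogits, nrow = 1L), cache$ln$Y, cache$p$W)
  lb <- lnBwd(g$dX, cache$ln)
  list(dCls = lb$dX[1L, ],
       grads = list(ln = list(gamma = lb$dgamma, beta = lb$dbeta),
                    W = g$dW, b = g$db))
}

## full forward pass with caches for backprop
milctFwd <- function(model, img) {
  bb <- ctFwd(img, model@spec, model@params$backbone)
  mlpF <- mlpHeadFwd(bb$F, model@params$mlp$F)
  mlpC <- mlpHeadFwd(bb$C, model@params$mlp$C)
  milF <- milBranchFwd(bb$F[-1L, , drop = FALSE], model@params$mil$F)
  milC <- milBranchFwd(bb$C[-1L, , drop = FALSE], model@params$mil$C)
  list(logits = list(mlpF = mlpF$logits, mlpC = mlpC$logits,
                     milF = milF$scores, milC = milC$scores),
       probs = list(mlpF = softmaxVec(mlpF$logits),
                    mlpC = softmaxVec(mlpC$logits),
                    milF = softmaxVec(milF$scores),
                    milC = softmaxVec(milC$scores)),
       alpha = list(F = milF$alpha, C = milC$alpha),
       cache = list(bb = bb$cache, mlpF = mlpF$cache, mlpC = mlpC$cache,
                    milF = milF$cache, milC = milC$cache))
}

## backward from gradients on the four heads' pre-softmax scores; returns
## the parameter-gradient tree and the Grad-CAM hook gradients
milctBwd <- function(model, fwd, dLogits) {
  hF <- mlpHeadBwd(dLogits$mlpF, fwd$cache$mlpF)
  hC <- mlpHeadBwd(dLogits$mlpC, fwd$cache$mlpC)
  bF <- milBranchBwd(dLogits$milF, fwd$cache$milF)
  bC <- milBranchBwd(dLogits$milC, fwd$cache$milC)
  dTokF <- rbind(hF$dCls, bF$dZ, deparse.level = 0L)
  dTokC <- rbind(hC$dCls, bC$dZ, deparse.level = 0L)
  cb <- ctBwd(dTokF, dTokC, fwd$cache$bb)
  list(grads = list(backbone = cb$grads,
                    mlp = list(F = hF$grads, C = hC$grads),
                    mil = list(F = bF$grads, C = bC$grads)),
       dHookF = cb$dHookF, dHookC = cb$dHookC)
}

validateProb <- function(p, what) {
  if (anyNA(p) || any(p < -1e-9) || any(p > 1 + 1e-9))
    stop(what, " must be a probability vector in [0,1]")
  if (abs(sum(p) - 1) > 1e-6)
    stop(what, " must sum to 1")
  invisible(TRUE)
}

#' Jointly weighted cross-entropy loss
#'
#' Per branch, the loss is
#' \code{-eta * sum(y * log p_mlp) - (1 - eta) * sum(y * log p_mil)},
#' i.e. a convex combination of the classification-token head's and the
#' bag-level head's cross-entropies; the two branch losses are summed.
#' Probabilities are floored at 1e-12 inside the logarithm.
#'
#' @param yGt one-hot ground-truth vector (length 2).
#' @param yMlp,yMil probability vectors of the two heads; either a single
#'   vector (one branch) or a list of per-branch vectors.
#' @param eta weight of the classification-token term, in [0, 1].
#' @return scalar loss.
#' @export
jointLoss <- function(yGt, yMlp, yMil, eta = 0.5) {
  if (eta < 0 || eta > 1) stop("eta must be in [0,1]")
  if (!is.list(yMlp)) yMlp <- list(yMlp)
  if (!is.list(yMil)) yMil <- list(yMil)
  stopifnot(length(yMlp) == length(yMil))
  total <- 0
  for (i in seq_along(yMlp)) {
    validateProb(yMlp[[i]], "yMlp")
    validateProb(yMil[[i]], "yMil")
    total <- total -
      eta * sum(yGt * log(pmax(yMlp[[i]], 1e-12))) -
      (1 - eta) * sum(yGt * log(pmax(yMil[[i]], 1e-12)))
  }
  total
}

## loss + exact gradients on the four heads' logits for one sample
milctLossAndGrad <- function(model, fwd, yGt) {
  eta <- model@spec@eta
  p <- fwd$probs
  loss <- jointLoss(yGt, list(p$mlpC, p$mlpF), list(p$milC, p$milF), eta)
  dLogits <- list(mlpF = eta * (p$mlpF - yGt),
                  mlpC = eta * (p$mlpC - yGt),
                  milF = (1 - eta) * (p$milF - yGt),
                  milC = (1 - eta) * (p$milC - yGt))
  list(loss = loss, dLogits = dLogits)
}

#' Fused prediction for one image
#'
#' Runs the full forward pass and combines the four heads:
#' \code{y_fused = normalize(eta * mean(p_mlp) + (1 - eta) * mean(p_mil))},
#' the means taken over the two branches, mirroring the loss weighting.
#' Class 1 is the positive (enhanced light reflex) class.
#'
#' @param model a \code{\link{MILCTModel-class}} object.
#' @param img raw image array.
#' @param tta average the fused probability over the 8 axis-aligned
#'   symmetries of the image (test-time augmentation); the per-head
#'   probabilities reported are those of the untransformed image.
#' @return list with \code{yMlp} and \code{yMil} (per-branch probability
#'   vectors, names \code{C} and \code{F}), \code{yFused} (final 2-class
#'   probability vector), and \code{yHat} (predicted class, 0 or 1).
#' @export
predictFused <- function(model, img, tta = FALSE) {
  stopifnot(is(model, "MILCTModel"))
  eta <- model@spec@eta
  fwd <- milctFwd(model, img)
  p <- fwd$probs
  fused <- fusedProb(p, eta)
  if (tta) {
    for (k in 1:7) {
      fk <- milctFwd(model, dihedralTransform(img, k))
      fused <- fused + fusedProb(fk$probs, eta)
    }
    fused <- fused / sum(fused)
  }
  list(yMlp = list(C = p$mlpC, F = p$mlpF),
       yMil = list(C = p$milC, F = p$milF),
       yFused = fused, yHat = which.max(fused) - 1L)
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds the parameter tree together with the model and
#' head specifications.
#'
#' @param model a \code{\link{MILCTModel-class}} object.
#' @param path checkpoint file path.
#' @return \code{saveMILCT} returns \code{path} invisibly;
#'   \code{loadMILCT} returns the restored model.
#' @export
saveMILCT <- function(model, path) {
  stopifnot(is(model, "MILCTModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveMILCT
#' @export
loadMILCT <- function(path) {
  model <- readRDS(path)
  stopifnot(is(model, "MILCTModel"))
  model
}
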