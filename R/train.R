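## Adam optimization, single-model training, stratified k-fold
## cross-validation and dataset summaries.

adamInit <- function(params) {
  list(m = treeZero(params), v = treeZero(params), t = 0L)
}

## Adam with additive L2 weight decay on the gradient
adamStep <- function(params, grads, state, lr = 1e-3, weightDecay = 5e-4,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  if (weightDecay > 0)
    grads <- treeMap2(function(g, p) g + weightDecay * p, grads, params)
  state$m <- treeMap2(function(m, g) beta1 * m + (1 - beta1) * g,
                      state$m, grads)
  state$v <- treeMap2(function(v, g) beta2 * v + (1 - beta2) * g^2,
                      state$v, grads)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  mh <- treeScale(state$m, 1 / bc1)
  vh <- treeScale(state$v, 1 / bc2)
  params <- treeMap2(function(p, u) p - u,
                     params,
                     treeMap2(function(m, v) lr * m / (sqrt(v) + eps),
                              mh, vh))
  list(params = params, state = state)
}

## one of the 8 axis-aligned symmetries (rotations by multiples of 90
## degrees, optionally mirrored); cheap, exact, and distribution-preserving
## for centred fundus discs
dihedralTransform <- function(img, k) {
  stopifnot(k >= 0L, k < 8L)
  if (k %/% 4L == 1L) img <- img[, dim(img)[2]:1, , drop = FALSE]
  for (r in seq_len(k %% 4L)) {
    img <- aperm(img, c(2L, 1L, 3L))
    img <- img[, dim(img)[2]:1, , drop = FALSE]
  }
  img
}

## random flip + arbitrary-angle rotation about the image centre, black
## fill; appropriate for a centred, rotation-symmetric field of view
randomRotation <- function(img, angle, mirror = FALSE) {
  if (mirror) img <- img[, dim(img)[2]:1, , drop = FALSE]
  out <- ebImageToRaw(EBImage::rotate(rawToEBImage(img), angle,
                                      output.dim = dim(img)[c(2L, 1L)],
                                      bg.col = 0))
  clip255(out)
}

oneHot <- function(label, nClasses = 2L) {
  y <- numeric(nClasses)
  y[label + 1L] <- 1
  y
}

fusedProb <- function(probs, eta) {
  fused <- eta * (probs$mlpC + probs$mlpF) / 2 +
    (1 - eta) * (probs$milC + probs$milF) / 2
  fused / sum(fused)
}

#' Train the model
#'
#' Minibatch Adam training of the full model under the jointly weighted
#' cross-entropy objective.  Defaults follow the reference protocol:
#' learning rate 1e-3, weight decay 5e-4, batch size 32; the epoch count
#' is set by the caller.  Training is deterministic for a fixed seed on a
#' fixed platform.
#'
#' @param samples list of samples, each a list with \code{image} (raw
#'   image array) and \code{label} (0/1).
#' @param model a \code{\link{MILCTModel-class}} to start from, or NULL to
#'   initialize one from \code{spec}/\code{milSpec}.
#' @param spec,milSpec specifications used when \code{model} is NULL.
#' @param epochs number of passes over the data.
#' @param lr,weightDecay,batchSize optimizer settings.
#' @param lrSchedule \code{"constant"} or \code{"cosine"} (cosine decay
#'   of the learning rate from \code{lr} to ~0 over \code{epochs}).
#' @param swaFrom optional epoch index; when given, the returned model's
#'   parameters are the average of the per-epoch parameters from that
#'   epoch onward (stochastic weight averaging), which stabilizes the
#'   endpoint of small-data runs.
#' @param seed integer seed controlling initialization and shuffling.
#' @param onlineAugment per-epoch random augmentation of each training
#'   image: FALSE (none), \code{"dihedral"} (or TRUE; one of the 8
#'   axis-aligned symmetries) or \code{"rotation"} (random flip followed
#'   by rotation at an arbitrary angle, black fill).  A strong regularizer
#'   for small datasets whose distribution has these symmetries.
#' @param verbose print per-epoch loss.
#' @return list with \code{model} (trained) and \code{log} (data frame of
#'   epoch, mean loss, training accuracy).
#' @export
trainMILCT <- function(samples, model = NULL, spec = tinyModelSpec(),
                       milSpec = MILHeadSpec(32L, 16L), epochs = 50L,
                       lr = 1e-3, weightDecay = 5e-4, batchSize = 32L,
                       seed = 1L, onlineAugment = FALSE,
                       lrSchedule = c("constant", "cosine"),
                       swaFrom = NULL, verbose = FALSE) {
  lrSchedule <- match.arg(lrSchedule)
  if (isTRUE(onlineAugment)) onlineAugment <- "dihedral"
  if (isFALSE(onlineAugment)) onlineAugment <- "none"
  onlineAugment <- match.arg(onlineAugment,
                             c("none", "dihedral", "rotation"))
  stopifnot(length(samples) > 0L)
  set.seed(as.integer(seed))
  if (is.null(model)) model <- buildModel(spec, milSpec)
  eta <- model@spec@eta
  opt <- adamInit(model@params)
  n <- length(samples)
  log <- data.frame(epoch = integer(), loss = numeric(), acc = numeric())
  swaSum <- NULL; swaN <- 0L
  for (ep in seq_len(epochs)) {
    epLr <- if (lrSchedule == "cosine")
      lr * 0.5 * (1 + cos(pi * (ep - 1) / epochs)) else lr
    ord <- sample.int(n)
    epLoss <- 0; epCorrect <- 0L
    for (start in seq(1L, n, by = batchSize)) {
      idx <- ord[start:min(start + batchSize - 1L, n)]
      gAcc <- NULL
      bLoss <- 0
      for (i in idx) {
        img <- samples[[i]]$image
        if (onlineAugment == "dihedral") {
          img <- dihedralTransform(img, sample.int(8L, 1L) - 1L)
        } else if (onlineAugment == "rotation") {
          img <- randomRotation(img, runif(1, 0, 360),
                                sample.int(2L, 1L) == 2L)
        }
        fwd <- milctFwd(model, img)
        y <- oneHot(samples[[i]]$label, model@spec@nClasses)
        lg <- milctLossAndGrad(model, fwd, y)
        if (!is.finite(lg$loss))
          stop("non-finite loss at epoch ", ep, ", sample ", i,
               "; aborting training")
        bLoss <- bLoss + lg$loss
        bw <- milctBwd(model, fwd, lg$dLogits)
        gAcc <- if (is.null(gAcc)) bw$grads else treeAdd(gAcc, bw$grads)
        pf <- fusedProb(fwd$probs, eta)
        epCorrect <- epCorrect +
          as.integer(which.max(pf) - 1L == samples[[i]]$label)
      }
      gAcc <- treeScale(gAcc, 1 / length(idx))
      upd <- adamStep(model@params, gAcc, opt, lr = epLr,
                      weightDecay = weightDecay)
      model@params <- upd$params
      opt <- upd$state
      epLoss <- epLoss + bLoss
    }
    if (!is.null(swaFrom) && ep >= swaFrom) {
      swaSum <- if (is.null(swaSum)) model@params else
        treeAdd(swaSum, model@params)
      swaN <- swaN + 1L
    }
    log <- rbind(log, data.frame(epoch = ep, loss = epLoss / n,
                                 acc = epCorrect / n))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  train acc %.3f",
                      ep, epLoss / n, epCorrect / n))
  }
  if (!is.null(swaFrom) && swaN > 0L)
    model@params <- treeScale(swaSum, 1 / swaN)
  list(model = model, log = log)
}

#' Evaluate a model on labelled samples
#'
#' Scores every sample with \code{\link{predictFused}}, thresholds by
#' argmax for the confusion matrix and keeps the positive-class
#' probability for ROC analysis.
#'
#' @param model a trained \code{\link{MILCTModel-class}}.
#' @param samples list of samples with \code{image} and \code{label}.
#' @param tta test-time augmentation, see \code{\link{predictFused}}.
#' @param threshold positive-class decision threshold on the fused
#'   probability (default 0.5; see \code{\link{calibrateThreshold}}).
#' @return list with \code{scores} (positive-class probabilities),
#'   \code{predicted}, \code{labels}, \code{cm} (2x2 confusion matrix,
#'   rows = truth), \code{metrics} (see \code{\link{computeMetrics}}) and
#'   \code{auc}/\code{roc} when both classes are present.
#' @export
evaluateModel <- function(model, samples, tta = FALSE, threshold = 0.5) {
  labels <- vapply(samples, function(s) as.integer(s$label), integer(1))
  scores <- numeric(length(samples))
  pred <- integer(length(samples))
  for (i in seq_along(samples)) {
    pr <- predictFused(model, samples[[i]]$image, tta = tta)
    scores[i] <- pr$yFused[2L]
    pred[i] <- as.integer(scores[i] > threshold)
  }
  cm <- confusionMatrix2(labels, pred)
  out <- list(scores = scores, predicted = pred, labels = labels,
              cm = cm, metrics = computeMetrics(cm))
  if (length(unique(labels)) == 2L) {
    rr <- rocAuc(scores, labels)
    out$auc <- rr$auc
    out$roc <- rr$points
  }
  out
}

#' Calibrate the decision threshold on training data
#'
#' Returns the median of the fused positive-class probabilities over the
#' given (training) samples.  With balanced classes this centres the
#' decision boundary of \code{\link{evaluateModel}} on the model's own
#' score distribution, correcting the miscalibration of raw probabilities
#' that small-sample training leaves behind.  Uses the training samples
#' only; no held-out information.
#'
#' @param model a trained \code{\link{MILCTModel-class}}.
#' @param samples the training samples.
#' @param tta test-time augmentation, see \code{\link{predictFused}}.
#' @return scalar threshold.
#' @export
calibrateThreshold <- function(model, samples, tta = FALSE) {
  scores <- vapply(samples, function(s)
    predictFused(model, s$image, tta = tta)$yFused[2L], numeric(1))
  median(scores)
}

#' Stratified k-fold assignment
#'
#' Partitions samples into \code{k} folds preserving the class proportions
#' (per-fold class counts differ from the proportional ideal by at most
#' one).  Deterministic for a fixed seed.
#'
#' @param labels integer vector of class labels, or a manifest data frame
#'   with a \code{label} column.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return integer vector of fold indices (1..k), one per sample.
#' @export
stratifiedKFold <- function(labels, k = 5L, seed = 1L) {
  if (is.data.frame(labels)) labels <- labels$label
  labels <- as.integer(labels)
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  if (any(table(labels) < k))
    stop("every class must have at least k members")
  set.seed(as.integer(seed))
  testIdx <- caret::createFolds(factor(labels), k = k)
  fold <- integer(length(labels))
  for (f in seq_along(testIdx)) fold[testIdx[[f]]] <- f
  fold
}

#' Cross-validated training and evaluation
#'
#' Runs stratified k-fold cross-validation: for each fold the model is
#' trained from scratch on the remaining folds (with optional
#' minority-class balancing augmentation applied to the training portion
#' only) and evaluated on the held-out fold.  Train/test disjointness is
#' asserted on every fold.
#'
#' @param samples list of samples with \code{image} and \code{label}.
#' @param k folds (default 5).
#' @param spec,milSpec model specifications.
#' @param epochs,lr,weightDecay,batchSize training settings (see
#'   \code{\link{trainMILCT}}).
#' @param balance apply \code{\link{augmentMinority}} to each training
#'   split (default TRUE).
#' @param onlineAugment,tta,calibrate per-epoch augmentation during
#'   training, test-time augmentation, and training-set threshold
#'   calibration (see \code{\link{trainMILCT}},
#'   \code{\link{predictFused}}, \code{\link{calibrateThreshold}}).
#' @param seed integer seed.
#' @return list with \code{folds} (per-fold evaluation results including
#'   fold index) and \code{summary} (data frame of mean and standard
#'   deviation across folds for accuracy and AUC).
#' @export
crossValidateMILCT <- function(samples, k = 5L, spec = tinyModelSpec(),
                               milSpec = MILHeadSpec(32L, 16L),
                               epochs = 20L, lr = 1e-3, weightDecay = 5e-4,
                               batchSize = 32L, balance = TRUE,
                               onlineAugment = FALSE, tta = FALSE,
                               calibrate = FALSE, seed = 1L) {
  labels <- vapply(samples, function(s) as.integer(s$label), integer(1))
  fold <- stratifiedKFold(labels, k = k, seed = seed)
  res <- vector("list", k)
  for (f in seq_len(k)) {
    trIdx <- which(fold != f)
    teIdx <- which(fold == f)
    stopifnot(length(intersect(trIdx, teIdx)) == 0L)
    tr <- samples[trIdx]
    if (balance && length(unique(labels[trIdx])) == 2L &&
        length(unique(table(labels[trIdx]))) > 1L)
      tr <- augmentMinority(tr, seed = seed + f)
    fit <- trainMILCT(tr, spec = spec, milSpec = milSpec, epochs = epochs,
                      lr = lr, weightDecay = weightDecay,
                      batchSize = batchSize, seed = seed + f,
                      onlineAugment = onlineAugment)
    thr <- if (calibrate) calibrateThreshold(fit$model, tr, tta = tta)
      else 0.5
    ev <- evaluateModel(fit$model, samples[teIdx], tta = tta,
                        threshold = thr)
    ev$fold <- f
    res[[f]] <- ev
  }
  accs <- vapply(res, function(r) r$metrics$acc, numeric(1))
  aucs <- vapply(res, function(r) if (is.null(r$auc)) NA_real_ else r$auc,
                 numeric(1))
  list(folds = res,
       summary = data.frame(
         metric = c("acc", "auc"),
         mean = c(mean(accs), mean(aucs, na.rm = TRUE)),
         sd = c(sd(accs), sd(aucs, na.rm = TRUE))))
}

#' Dataset class-balance summary
#'
#' Per-class counts and percentage proportions (2 decimals), overall and
#' per split when a \code{split} column is present.
#'
#' @param manifest data frame with a \code{label} column and optionally a
#'   \code{split} column.
#' @return list with \code{overall} (data frame of label, count,
#'   proportion in percent), \code{bySplit} (data frame of per-split
#'   counts, or NULL) and \code{total}.
#' @export
datasetSummary <- function(manifest) {
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    stop("manifest must be a nonempty data frame")
  total <- nrow(manifest)
  tab <- table(manifest$label)
  overall <- data.frame(label = names(tab),
                        count = as.integer(tab),
                        proportion = round(as.integer(tab) / total * 100, 2),
                        stringsAsFactors = FALSE)
  bySplit <- NULL
  if (!is.null(manifest$split)) {
    st <- table(manifest$label, manifest$split)
    bySplit <- as.data.frame.matrix(st)
    bySplit <- cbind(label = rownames(bySplit), bySplit,
                     stringsAsFactors = FALSE)
    rownames(bySplit) <- NULL
  }
  list(overall = overall, bySplit = bySplit, total = total)
}
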