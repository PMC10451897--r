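## Classification metrics and ROC analysis.

#' Confusion matrix for binary predictions
#'
#' @param labels true labels (0/1).
#' @param predicted predicted labels (0/1).
#' @return 2x2 integer matrix, rows = true class, columns = predicted
#'   class, dimnames 0/1.
#' @export
confusionMatrix2 <- function(labels, predicted) {
  cm <- table(factor(labels, levels = c(0L, 1L)),
              factor(predicted, levels = c(0L, 1L)))
  m <- matrix(as.integer(cm), 2L, 2L,
              dimnames = list(true = c("0", "1"), pred = c("0", "1")))
  m
}

safeRatio <- function(num, den, what) {
  if (den == 0) {
    warning(what, " undefined (zero denominator); reported as NaN")
    return(NaN)
  }
  num / den
}

#' Classification metrics from a confusion matrix
#'
#' Per class: precision TP/(TP+FP), sensitivity TP/(TP+FN), specificity
#' TN/(TN+FP), and the F1 score both as the harmonic mean of precision and
#' sensitivity (the headline variant) and as their arithmetic mean.
#' Accuracy is global; macro rows are unweighted means over the two
#' classes.  All values are percentages; undefined ratios are flagged as
#' NaN with a warning, never silently zero.
#'
#' @param cm 2x2 confusion matrix, rows = true class, columns = predicted.
#' @return list with \code{acc}, \code{perClass} (data frame with pre,
#'   sen, spe, f1, f1Arith per class) and \code{macro} (unweighted means).
#' @export
computeMetrics <- function(cm) {
  stopifnot(is.matrix(cm), all(dim(cm) == 2L))
  if (any(cm < 0) || sum(cm) == 0)
    stop("confusion matrix must be nonnegative with a positive total")
  acc <- sum(diag(cm)) / sum(cm) * 100
  per <- lapply(1:2, function(c) {
    tp <- cm[c, c]
    fp <- sum(cm[-c, c])
    fn <- sum(cm[c, -c])
    tn <- sum(cm[-c, -c])
    pre <- safeRatio(tp, tp + fp, paste0("precision(class ", c - 1L, ")")) * 100
    sen <- safeRatio(tp, tp + fn, paste0("sensitivity(class ", c - 1L, ")")) * 100
    spe <- safeRatio(tn, tn + fp, paste0("specificity(class ", c - 1L, ")")) * 100
    f1 <- if (is.nan(pre) || is.nan(sen) || (pre + sen) == 0) NaN else
      2 * pre * sen / (pre + sen)
    data.frame(class = c - 1L, pre = pre, sen = sen, spe = spe, f1 = f1,
               f1Arith = (pre + sen) / 2)
  })
  perClass <- do.call(rbind, per)
  macro <- data.frame(pre = mean(perClass$pre), sen = mean(perClass$sen),
                      spe = mean(perClass$spe), f1 = mean(perClass$f1),
                      f1Arith = mean(perClass$f1Arith))
  list(acc = acc, perClass = perClass, macro = macro)
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the unique scores and computes the area under
#' the ROC curve by the trapezoid rule, with tied scores handled by rank
#' averaging (equivalently: the probability that a random positive
#' outscores a random negative, ties counting one half).
#'
#' @param scores positive-class probabilities (or any monotone score).
#' @param labels true labels (0/1); both classes must be present.
#' @return list with \code{points} (data frame of fpr, tpr, ordered by
#'   fpr) and \code{auc}.
#' @export
rocAuc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present for ROC analysis")
  r <- pROC::roc(response = labels, predictor = as.numeric(scores),
                 levels = c(0L, 1L), direction = "<", quiet = TRUE)
  pts <- data.frame(fpr = 1 - r$specificities, tpr = r$sensitivities)
  pts <- pts[order(pts$fpr, pts$tpr), ]
  rownames(pts) <- NULL
  list(points = pts, auc = as.numeric(r$auc))
}
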