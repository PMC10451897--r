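## Attention-based multiple-instance head.  The image is the bag, the
## final-layer patch tokens of a branch are its instances.  Instances are
## embedded into a low-dimensional nonnegative representation, pooled by a
## learned softmax attention, and classified by a single linear map.
## Following the defining equations, the linear maps carry no bias terms
## (the layer-norm offsets provide the shifts).

initMILBranchParams <- function(d, milSpec) {
  m <- milSpec@embedDim; l <- milSpec@attnDim
  list(Wlin = matrix(truncNormal(d * m, sd = 1 / sqrt(d)), d, m),
       lnE = initLayerNorm(m),
       W1 = matrix(truncNormal(m * l, sd = 1 / sqrt(m)), m, l),
       lnA = initLayerNorm(l),
       w2 = truncNormal(l, sd = 1 / sqrt(l)),
       Wbag = matrix(truncNormal(m * milSpec@nClasses, sd = 1 / sqrt(m)), m,
                     milSpec@nClasses))
}

#' Instance embedding
#'
#' Maps each instance (patch-token feature vector) through a linear layer,
#' layer normalization and a ReLU: \code{h_i = max(LN(W' z_i), 0)}.
#'
#' @param Z instance matrix (\code{n x d}), one instance per row.
#' @param W weight matrix \code{d x m}.
#' @param gamma,beta layer-norm parameters over the \code{m} embedding
#'   channels (defaults: ones / zeros).
#' @return \code{n x m} matrix of nonnegative instance embeddings.
#' @export
instanceEmbed <- function(Z, W, gamma = rep(1, ncol(W)),
                          beta = numeric(ncol(W))) {
  if (!is.matrix(Z) || nrow(Z) < 1L) stop("Z must be a nonempty matrix")
  if (nrow(W) != ncol(Z)) stop("W must map the instance dimension")
  pmax(lnFwd(Z %*% W, gamma, beta)$Y, 0)
}

#' Attention aggregation
#'
#' Scores each instance embedding with a two-layer gated scorer
#' \code{e_i = w2' max(LN(h_i W1), 0)}, normalizes the scores with a
#' softmax over the instances, and returns the attention-weighted bag
#' representation \code{A = sum_i alpha_i h_i}.
#'
#' @param H instance embedding matrix (\code{n x m}).
#' @param W1 weight matrix \code{m x l}.
#' @param w2 weight vector of length \code{l}.
#' @param gamma,beta layer-norm parameters over the \code{l} hidden
#'   channels.
#' @return list with \code{alpha} (length-\code{n} attention weights
#'   summing to 1) and \code{A} (length-\code{m} bag representation).
#' @export
attentionAggregate <- function(H, W1, w2, gamma = rep(1, ncol(W1)),
                               beta = numeric(ncol(W1))) {
  if (!is.matrix(H) || nrow(H) < 1L) stop("H must hold at least one instance")
  Rl <- pmax(lnFwd(H %*% W1, gamma, beta)$Y, 0)
  alpha <- softmaxVec(as.vector(Rl %*% w2))
  list(alpha = alpha, A = as.vector(crossprod(H, alpha)))
}

#' Bag-level classification
#'
#' Single linear map from the aggregated bag representation to per-class
#' scores.
#'
#' @param A bag representation vector of length \code{m}.
#' @param Wbag weight matrix \code{m x nClasses}.
#' @return per-class score vector.
#' @export
bagClassify <- function(A, Wbag) {
  if (length(A) != nrow(Wbag)) stop("Wbag must map the bag representation")
  drop(matrix(A, nrow = 1L) %*% Wbag)
}

## cached forward of one branch head, for backprop
milBranchFwd <- function(Z, p) {
  M <- Z %*% p$Wlin
  le <- lnFwd(M, p$lnE$gamma, p$lnE$beta)
  H <- pmax(le$Y, 0)
  G <- H %*% p$W1
  la <- lnFwd(G, p$lnA$gamma, p$lnA$beta)
  Rl <- pmax(la$Y, 0)
  e <- as.vector(Rl %*% p$w2)
  alpha <- softmaxVec(e)
  A <- as.vector(crossprod(H, alpha))
  scores <- drop(matrix(A, nrow = 1L) %*% p$Wbag)
  list(scores = scores, alpha = alpha, A = A,
       cache = list(Z = Z, le = le, H = H, la = la, Rl = Rl,
                    alpha = alpha, A = A, p = p))
}

milBranchBwd <- function(dScores, cache) {
  p <- cache$p
  H <- cache$H; alpha <- cache$alpha
  dWbag <- outer(cache$A, dScores)
  dA <- as.vector(p$Wbag %*% dScores)
  dH <- outer(alpha, dA)
  dalpha <- as.vector(H %*% dA)
  de <- alpha * (dalpha - sum(dalpha * alpha))
  dRl <- outer(de, p$w2)
  dw2 <- as.vector(crossprod(cache$Rl, de))
  dla <- dRl * (cache$la$Y > 0)
  lab <- lnBwd(dla, cache$la)
  dH <- dH + lab$dX %*% t(p$W1)
  dW1 <- crossprod(H, lab$dX)
  dle <- dH * (cache$le$Y > 0)
  leb <- lnBwd(dle, cache$le)
  dZ <- leb$dX %*% t(p$Wlin)
  dWlin <- crossprod(cache$Z, leb$dX)
  list(dZ = dZ,
       grads = list(Wlin = dWlin,
                    lnE = list(gamma = leb$dgamma, beta = leb$dbeta),
                    W1 = dW1,
                    lnA = list(gamma = lab$dgamma, beta = lab$dbeta),
                    w2 = dw2, Wbag = dWbag))
}

#' Bag-level head over both branches
#'
#' Runs instance embedding, attention aggregation and bag classification
#' on the patch tokens of each branch (classification tokens are excluded
#' from the bags) and concatenates the per-branch class scores, coarse
#' branch first.
#'
#' @param seqF,seqC final token sequences of the fine and coarse branch
#'   (lists with a \code{tokens} matrix, classification token in row 1).
#' @param params bag-head parameters: list with per-branch elements
#'   \code{F} and \code{C} (see \code{\link{buildModel}}).
#' @return list with per-branch score vectors \code{C} and \code{F}, their
#'   concatenation \code{Pmil} (coarse first), and the per-branch
#'   attention weights \code{alphaC}, \code{alphaF}.
#' @export
milHeadForward <- function(seqF, seqC, params) {
  fF <- milBranchFwd(seqF$tokens[-1L, , drop = FALSE], params$F)
  fC <- milBranchFwd(seqC$tokens[-1L, , drop = FALSE], params$C)
  list(C = fC$scores, F = fF$scores,
       Pmil = c(fC$scores, fF$scores),
       alphaC = fC$alpha, alphaF = fF$alpha)
}
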