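## Dense-layer primitives used by the backbone and heads.  Every forward
## function has a matching backward that consumes the forward cache; the
## whole network's gradients are exact (verified against finite differences
## in the test suite).  Token matrices are (tokens x channels).

## -- initialization ---------------------------------------------------------

## truncated normal (+/- 2 sd); weight matrices use fan-in scaling
## (sd = 1/sqrt(fan_in)), tokens and position embeddings a small fixed sd
truncNormal <- function(n, sd = 0.02) {
  qnorm(runif(n, pnorm(-2), pnorm(2))) * sd
}

initLinear <- function(dIn, dOut, bias = TRUE) {
  p <- list(W = matrix(truncNormal(dIn * dOut, sd = 1 / sqrt(dIn)), dIn, dOut))
  if (bias) p$b <- numeric(dOut)
  p
}

initLayerNorm <- function(d) {
  list(gamma = rep(1, d), beta = numeric(d))
}

initAttention <- function(d) {
  sd <- 1 / sqrt(d)
  list(Wq = matrix(truncNormal(d * d, sd), d, d), bq = numeric(d),
       Wk = matrix(truncNormal(d * d, sd), d, d), bk = numeric(d),
       Wv = matrix(truncNormal(d * d, sd), d, d), bv = numeric(d),
       Wo = matrix(truncNormal(d * d, sd), d, d), bo = numeric(d))
}

## -- parameter-tree helpers -------------------------------------------------

paramCountTree <- function(x) {
  if (is.list(x)) sum(vapply(x, paramCountTree, numeric(1))) else length(x)
}

treeMap <- function(f, x) {
  if (is.list(x)) lapply(x, function(el) treeMap(f, el)) else f(x)
}

treeMap2 <- function(f, a, b) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a)) out[[i]] <- treeMap2(f, a[[i]], b[[i]])
    out
  } else f(a, b)
}

treeZero <- function(x) treeMap(function(v) v * 0, x)

treeAdd <- function(a, b) treeMap2(`+`, a, b)

treeScale <- function(x, s) treeMap(function(v) v * s, x)

## -- elementary layers ------------------------------------------------------

addBias <- function(X, b) sweep(X, 2L, b, "+")

linearFwd <- function(X, W, b = NULL) {
  Y <- X %*% W
  if (!is.null(b)) Y <- addBias(Y, b)
  Y
}

linearBwd <- function(dY, X, W, bias = TRUE) {
  g <- list(dX = dY %*% t(W), dW = crossprod(X, dY))
  if (bias) g$db <- colSums(dY)
  g
}

#' Layer normalization
#'
#' Normalizes each token (row) to zero mean and unit variance over the
#' channel dimension, then applies the learnable affine map
#' \code{gamma * xhat + beta}.  The variance is the population variance and
#' \code{eps} is added inside the square root.
#'
#' @param x numeric matrix (tokens x channels) or a single token vector.
#' @param gamma,beta learnable scale and offset vectors, one entry per
#'   channel.
#' @param eps numerical stabilizer (default 1e-6).
#' @return matrix (or vector) of the same shape.
#' @export
layerNorm <- function(x, gamma = rep(1, d), beta = numeric(d), eps = 1e-6) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, nrow = 1L)
  d <- ncol(x)
  if (eps <= 0) stop("eps must be > 0")
  out <- lnFwd(x, gamma, beta, eps)$Y
  if (vec) out[1L, ] else out
}

lnFwd <- function(X, gamma, beta, eps = 1e-6) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  Y <- addBias(sweep(xhat, 2L, gamma, "*"), beta)
  list(Y = Y, xhat = xhat, inv = inv, gamma = gamma)
}

lnBwd <- function(dY, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dY, 2L, cache$gamma, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  list(dX = (dxhat - m1 - xhat * m2) * cache$inv,
       dgamma = colSums(dY * xhat), dbeta = colSums(dY))
}

geluFwd <- function(x) x * pnorm(x)

geluBwd <- function(dY, x) dY * (pnorm(x) + x * dnorm(x))

softmaxRows <- function(S) {
  E <- exp(S - apply(S, 1L, max))
  E / rowSums(E)
}

softmaxVec <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

## backward through row-wise softmax given its output A
softmaxRowsBwd <- function(dA, A) {
  A * (dA - rowSums(dA * A))
}

## -- multi-head attention ---------------------------------------------------

## generic scaled dot-product multi-head attention; Xq supplies the
## queries, Xkv the keys and values (Xq == Xkv for self-attention).
attnFwd <- function(Xq, Xkv, w, nHeads) {
  d <- ncol(Xq)
  if (d %% nHeads != 0L) stop("embedding dim not divisible by head count")
  dh <- d %/% nHeads
  scal <- 1 / sqrt(dh)
  Q <- linearFwd(Xq, w$Wq, w$bq)
  K <- linearFwd(Xkv, w$Wk, w$bk)
  V <- linearFwd(Xkv, w$Wv, w$bv)
  O <- matrix(0, nrow(Xq), d)
  Ahs <- vector("list", nHeads)
  for (h in seq_len(nHeads)) {
    idx <- ((h - 1L) * dh + 1L):(h * dh)
    A <- softmaxRows(Q[, idx, drop = FALSE] %*% t(K[, idx, drop = FALSE]) * scal)
    Ahs[[h]] <- A
    O[, idx] <- A %*% V[, idx, drop = FALSE]
  }
  out <- linearFwd(O, w$Wo, w$bo)
  list(out = out,
       cache = list(Xq = Xq, Xkv = Xkv, Q = Q, K = K, V = V, O = O,
                    A = Ahs, w = w, nHeads = nHeads, dh = dh, scal = scal))
}

attnBwd <- function(dOut, cache) {
  w <- cache$w
  dO <- dOut %*% t(w$Wo)
  dw <- list(Wq = NULL, bq = NULL, Wk = NULL, bk = NULL,
             Wv = NULL, bv = NULL,
             Wo = crossprod(cache$O, dOut), bo = colSums(dOut))
  dQ <- matrix(0, nrow(cache$Q), ncol(cache$Q))
  dK <- matrix(0, nrow(cache$K), ncol(cache$K))
  dV <- matrix(0, nrow(cache$V), ncol(cache$V))
  for (h in seq_len(cache$nHeads)) {
    idx <- ((h - 1L) * cache$dh + 1L):(h * cache$dh)
    A <- cache$A[[h]]
    Vh <- cache$V[, idx, drop = FALSE]
    dOh <- dO[, idx, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, idx] <- crossprod(A, dOh)
    dS <- softmaxRowsBwd(dA, A) * cache$scal
    dQ[, idx] <- dS %*% cache$K[, idx, drop = FALSE]
    dK[, idx] <- crossprod(dS, cache$Q[, idx, drop = FALSE])
  }
  gq <- linearBwd(dQ, cache$Xq, w$Wq)
  gk <- linearBwd(dK, cache$Xkv, w$Wk)
  gv <- linearBwd(dV, cache$Xkv, w$Wv)
  dw$Wq <- gq$dW; dw$bq <- gq$db
  dw$Wk <- gk$dW; dw$bk <- gk$db
  dw$Wv <- gv$dW; dw$bv <- gv$db
  list(dXq = gq$dX, dXkv = gk$dX + gv$dX, dw = dw)
}

#' Multi-head self-attention
#'
#' Standard per-head scaled dot-product self-attention
#' \code{softmax(Q K' / sqrt(d/t)) V} with learned query/key/value and
#' output projections.  Shape is preserved and every attention row is a
#' probability distribution over the key tokens.
#'
#' @param tokens numeric matrix (tokens x channels).
#' @param weights list with entries \code{Wq, bq, Wk, bk, Wv, bv, Wo, bo}
#'   (see \code{\link{buildModel}} for how the package initializes them).
#' @param nHeads number of heads; the channel dimension must be divisible
#'   by it.
#' @return list with \code{out} (transformed tokens, same shape) and
#'   \code{attention} (list of per-head row-stochastic attention matrices).
#' @export
mhsa <- function(tokens, weights, nHeads = 1L) {
  f <- attnFwd(tokens, tokens, weights, nHeads)
  list(out = f$out, attention = f$cache$A)
}
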