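## Shared fixtures: tiny model specs, random images and a finite-difference
## utility used by the gradient-correctness tests.

gradSpec <- function() {
  ModelSpec(
    fBranch = BranchSpec(8L, 24L, 8L, depth = 1L, nHeads = 2L,
                         ffnExpansion = 2L),
    cBranch = BranchSpec(12L, 24L, 12L, depth = 2L, nHeads = 2L,
                         ffnExpansion = 2L),
    nReps = 2L, eta = 0.6)
}

gradMilSpec <- function() MILHeadSpec(6L, 4L)

randomImage <- function(s = 24L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(runif(s * s * 3, 0, 255), c(s, s, 3L))
}

## flatten a parameter tree into leaf access paths
paramLeaves <- function(tree, prefix = "") {
  if (is.list(tree)) {
    out <- list()
    for (i in seq_along(tree)) {
      nm <- if (!is.null(names(tree)) && nzchar(names(tree)[i]))
        paste0(prefix, "$", names(tree)[i]) else
        paste0(prefix, "[[", i, "]]")
      out <- c(out, paramLeaves(tree[[i]], nm))
    }
    out
  } else list(list(path = prefix, len = length(tree)))
}

leafGet <- function(tree, path) eval(parse(text = paste0("tree", path)))

leafSet <- function(tree, path, val) {
  eval(parse(text = paste0("tree", path, " <- val")))
  tree
}

## independent layer-norm oracle (population variance, eps inside sqrt)
lnOracle <- function(x, gamma, beta, eps = 1e-6) {
  mu <- mean(x)
  v <- mean((x - mu)^2)
  (x - mu) / sqrt(v + eps) * gamma + beta
}

softmaxOracle <- function(s) {
  e <- exp(s - max(s))
  e / sum(e)
}

## brute-force oracle for the whole bag head, written directly from the
## defining per-instance formulas with explicit loops
milOracle <- function(Z, p) {
  n <- nrow(Z)
  H <- matrix(0, n, ncol(p$Wlin))
  for (i in seq_len(n))
    H[i, ] <- pmax(lnOracle(as.vector(Z[i, ] %*% p$Wlin),
                            p$lnE$gamma, p$lnE$beta), 0)
  e <- numeric(n)
  for (i in seq_len(n))
    e[i] <- sum(pmax(lnOracle(as.vector(H[i, ] %*% p$W1),
                              p$lnA$gamma, p$lnA$beta), 0) * p$w2)
  alpha <- softmaxOracle(e)
  A <- numeric(ncol(H))
  for (i in seq_len(n)) A <- A + alpha[i] * H[i, ]
  scores <- as.vector(A %*% p$Wbag)
  list(H = H, alpha = alpha, A = A, scores = scores)
}

## step-by-step oracle for one cross-scale fusion direction (single head)
fuseOracle <- function(clsOwn, patchesOther, p) {
  pc <- lnOracle(clsOwn, p$lnP$gamma, p$lnP$beta) %*% p$proj$W + p$proj$b
  xhat <- rbind(pc, patchesOther)
  xn <- t(apply(xhat, 1, lnOracle, gamma = p$lnX$gamma, beta = p$lnX$beta))
  nr <- nrow(xn)
  Q <- xn[1, , drop = FALSE] %*% p$attn$Wq + p$attn$bq
  K <- xn %*% p$attn$Wk + rep(1, nr) %o% p$attn$bk
  V <- xn %*% p$attn$Wv + rep(1, nr) %o% p$attn$bv
  A <- softmaxOracle(as.vector(Q %*% t(K)) / sqrt(ncol(xn)))
  att <- (matrix(A, 1) %*% V) %*% p$attn$Wo + p$attn$bo
  u <- pc + att
  as.vector(lnOracle(as.vector(u), p$lnB$gamma, p$lnB$beta) %*% p$back$W +
              p$back$b)
}
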