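## Two-branch cross-scale transformer backbone.  Each branch embeds
## non-overlapping patches of its own size, prepends a learned
## classification token and adds learned position embeddings once; then
## `nReps` times: the per-branch encoder stacks run, followed by one
## multi-head cross-scale attention fusion in which each branch's
## classification token (as sole query) attends over the other branch's
## patch tokens.  Patch tokens pass through the fusion unchanged.

## -- parameter initialization ----------------------------------------------

initEmbedParams <- function(spec) {
  q <- spec@embedDim
  dIn <- 3L * spec@patchSize^2
  n <- numPatches(spec)
  list(W = matrix(truncNormal(dIn * q, sd = 1 / sqrt(dIn)), dIn, q),
       b = numeric(q),
       cls = truncNormal(q), pos = matrix(truncNormal((n + 1L) * q), n + 1L, q))
}

initBlockParams <- function(q, e) {
  list(ln1 = initLayerNorm(q), attn = initAttention(q),
       ln2 = initLayerNorm(q),
       ffn = list(W1 = matrix(truncNormal(q * e * q, sd = 1 / sqrt(q)),
                              q, e * q),
                  b1 = numeric(e * q),
                  W2 = matrix(truncNormal(e * q * q, sd = 1 / sqrt(e * q)),
                              e * q, q),
                  b2 = numeric(q)))
}

## fusion module for one direction: project own cls into the other
## branch's dimension, attend over the other branch's tokens, project back
initFuseParams <- function(qOwn, qOther) {
  list(lnP = initLayerNorm(qOwn),
       proj = list(W = matrix(truncNormal(qOwn * qOther, sd = 1 / sqrt(qOwn)),
                              qOwn, qOther),
                   b = numeric(qOther)),
       lnX = initLayerNorm(qOther),
       attn = initAttention(qOther),
       lnB = initLayerNorm(qOther),
       back = list(W = matrix(truncNormal(qOther * qOwn,
                                          sd = 1 / sqrt(qOther)),
                              qOther, qOwn),
                   b = numeric(qOwn)))
}

initBackboneParams <- function(spec) {
  fs <- spec@fBranch; cs <- spec@cBranch
  reps <- vector("list", spec@nReps)
  for (r in seq_len(spec@nReps)) {
    reps[[r]] <- list(
      F = lapply(seq_len(fs@depth), function(i)
        initBlockParams(fs@embedDim, fs@ffnExpansion)),
      C = lapply(seq_len(cs@depth), function(i)
        initBlockParams(cs@embedDim, cs@ffnExpansion)),
      fuse = list(F = initFuseParams(fs@embedDim, cs@embedDim),
                  C = initFuseParams(cs@embedDim, fs@embedDim)))
  }
  list(embedF = initEmbedParams(fs), embedC = initEmbedParams(cs),
       reps = reps,
       finalLN = list(F = initLayerNorm(fs@embedDim),
                      C = initLayerNorm(cs@embedDim)))
}

## -- patch embedding --------------------------------------------------------

## flatten non-overlapping p x p patches, patch-grid row-major, each patch
## vectorized in array order (rows, columns, channels)
patchify <- function(img, p) {
  s <- dim(img)[1]
  g <- s %/% p
  P <- matrix(0, g * g, 3L * p * p)
  k <- 0L
  for (gi in seq_len(g)) for (gj in seq_len(g)) {
    k <- k + 1L
    P[k, ] <- as.vector(img[((gi - 1L) * p + 1L):(gi * p),
                            ((gj - 1L) * p + 1L):(gj * p), ])
  }
  P
}

#' Patch embedding
#'
#' Resizes the image to the branch's input size, splits it into
#' non-overlapping square patches, projects each flattened patch linearly
#' into the branch's embedding dimension, prepends the learned
#' classification token and adds the learned position embeddings.  Pixel
#' intensities are rescaled to [-1, 1] before projection (the usual
#' transformer input normalization; an uncentred all-positive input leaves
#' every patch token dominated by the shared brightness direction).
#'
#' @param img raw image array.
#' @param spec a \code{\link{BranchSpec}}.
#' @param params embedding parameters (\code{W}, \code{b}, \code{cls},
#'   \code{pos}); defaults to a fresh random initialization.
#' @return a token sequence: list with \code{tokens}
#'   (\code{(n+1) x q} matrix, classification token in row 1) and
#'   \code{nPatches}.
#' @export
patchEmbed <- function(img, spec, params = initEmbedParams(spec)) {
  assertRawImage(img)
  if (spec@inputSize %% spec@patchSize != 0L)
    stop("input size must be divisible by the patch size")
  img <- resizeImage(img, spec@inputSize)
  P <- patchify(img / 127.5 - 1, spec@patchSize)
  X <- linearFwd(P, params$W, params$b)
  tokens <- rbind(params$cls, X, deparse.level = 0L) + params$pos
  list(tokens = tokens, nPatches = nrow(P), patches = P)
}

## -- encoder block ----------------------------------------------------------

encBlockFwd <- function(X, p, nHeads) {
  l1 <- lnFwd(X, p$ln1$gamma, p$ln1$beta)
  at <- attnFwd(l1$Y, l1$Y, p$attn, nHeads)
  y <- X + at$out
  l2 <- lnFwd(y, p$ln2$gamma, p$ln2$beta)
  H1 <- linearFwd(l2$Y, p$ffn$W1, p$ffn$b1)
  G <- geluFwd(H1)
  H2 <- linearFwd(G, p$ffn$W2, p$ffn$b2)
  list(out = y + H2,
       cache = list(l1 = l1, at = at$cache, y = y, l2 = l2, H1 = H1, G = G,
                    p = p))
}

encBlockBwd <- function(dOut, cache) {
  p <- cache$p
  g2 <- linearBwd(dOut, cache$G, p$ffn$W2)
  dH1 <- geluBwd(g2$dX, cache$H1)
  g1 <- linearBwd(dH1, cache$l2$Y, p$ffn$W1)
  l2b <- lnBwd(g1$dX, cache$l2)
  dy <- dOut + l2b$dX
  ab <- attnBwd(dy, cache$at)
  l1b <- lnBwd(ab$dXq + ab$dXkv, cache$l1)
  list(dX = dy + l1b$dX,
       grads = list(ln1 = list(gamma = l1b$dgamma, beta = l1b$dbeta),
                    attn = ab$dw,
                    ln2 = list(gamma = l2b$dgamma, beta = l2b$dbeta),
                    ffn = list(W1 = g1$dW, b1 = g1$db,
                               W2 = g2$dW, b2 = g2$db)))
}

#' Transformer encoder block
#'
#' Pre-norm residual block: \code{y = x + MHSA(LN(x))} followed by
#' \code{y + FFN(LN(y))}, where the feed-forward network expands the
#' channel dimension by the branch's expansion factor with a GELU
#' nonlinearity in between.
#'
#' @param x token matrix \code{(n+1) x q}.
#' @param params block parameter list (\code{ln1}, \code{attn}, \code{ln2},
#'   \code{ffn}).
#' @param nHeads attention heads.
#' @return transformed token matrix of identical shape.
#' @export
encoderBlock <- function(x, params, nHeads = 1L) {
  encBlockFwd(x, params, nHeads)$out
}

## -- cross-scale fusion -----------------------------------------------------

fuseDirFwd <- function(clsOwn, patchesOther, p, nHeads) {
  lp <- lnFwd(matrix(clsOwn, nrow = 1L), p$lnP$gamma, p$lnP$beta)
  pc <- linearFwd(lp$Y, p$proj$W, p$proj$b)
  xhat <- rbind(pc, patchesOther, deparse.level = 0L)
  lx <- lnFwd(xhat, p$lnX$gamma, p$lnX$beta)
  at <- attnFwd(lx$Y[1L, , drop = FALSE], lx$Y, p$attn, nHeads)
  u <- pc + at$out
  lb <- lnFwd(u, p$lnB$gamma, p$lnB$beta)
  z <- linearFwd(lb$Y, p$back$W, p$back$b)
  list(cls = z[1L, ], attention = at$cache$A,
       cache = list(lp = lp, pc = pc, lx = lx, at = at$cache, lb = lb,
                    nOther = nrow(patchesOther), p = p))
}

fuseDirBwd <- function(dCls, cache) {
  p <- cache$p
  gB <- linearBwd(matrix(dCls, nrow = 1L), cache$lb$Y, p$back$W)
  lbb <- lnBwd(gB$dX, cache$lb)
  du <- lbb$dX
  ab <- attnBwd(du, cache$at)
  dlxY <- ab$dXkv
  dlxY[1L, ] <- dlxY[1L, ] + ab$dXq[1L, ]
  lxb <- lnBwd(dlxY, cache$lx)
  dpc <- du + lxb$dX[1L, , drop = FALSE]
  dPatchesOther <- lxb$dX[-1L, , drop = FALSE]
  gP <- linearBwd(dpc, cache$lp$Y, p$proj$W)
  lpb <- lnBwd(gP$dX, cache$lp)
  list(dClsOwn = lpb$dX[1L, ], dPatchesOther = dPatchesOther,
       grads = list(lnP = list(gamma = lpb$dgamma, beta = lpb$dbeta),
                    proj = list(W = gP$dW, b = gP$db),
                    lnX = list(gamma = lxb$dgamma, beta = lxb$dbeta),
                    attn = ab$dw,
                    lnB = list(gamma = lbb$dgamma, beta = lbb$dbeta),
                    back = list(W = gB$dW, b = gB$db)))
}

#' Multi-head cross-scale attention fusion
#'
#' For each branch, the classification token is projected into the other
#' branch's dimension, concatenated with the other branch's patch tokens,
#' and used as the sole attention query over that concatenation; the
#' attended result (plus a residual on the projected token) is projected
#' back and replaces the classification token.  Patch tokens of both
#' branches pass through unchanged, and each direction's attention map has
#' exactly one row, so cost grows linearly in the other branch's token
#' count.
#'
#' @param seqF,seqC token sequences (lists with a \code{tokens} matrix,
#'   classification token in row 1) of the fine and coarse branch.
#' @param params fusion parameters: list with elements \code{F} and
#'   \code{C}, one per updated branch (see \code{\link{buildModel}}).
#' @param nHeadsF,nHeadsC head counts of the fine and coarse branch; the
#'   direction updating branch X runs its attention in the other branch's
#'   dimension with the other branch's head count.
#' @return list with updated sequences \code{F} and \code{C} and
#'   \code{attention}, the per-direction lists of 1-row attention maps.
#' @export
crossAttentionFuse <- function(seqF, seqC, params, nHeadsF = 1L,
                               nHeadsC = 1L) {
  fF <- fuseDirFwd(seqF$tokens[1L, ], seqC$tokens[-1L, , drop = FALSE],
                   params$F, nHeadsC)
  fC <- fuseDirFwd(seqC$tokens[1L, ], seqF$tokens[-1L, , drop = FALSE],
                   params$C, nHeadsF)
  outF <- seqF$tokens; outF[1L, ] <- fF$cls
  outC <- seqC$tokens; outC[1L, ] <- fC$cls
  list(F = list(tokens = outF, nPatches = nrow(outF) - 1L),
       C = list(tokens = outC, nPatches = nrow(outC) - 1L),
       attention = list(F = fF$attention, C = fC$attention))
}

## -- full backbone ----------------------------------------------------------

ctFwd <- function(img, spec, params) {
  fs <- spec@fBranch; cs <- spec@cBranch
  embF <- patchEmbed(img, fs, params$embedF)
  embC <- patchEmbed(img, cs, params$embedC)
  XF <- embF$tokens; XC <- embC$tokens
  repCaches <- vector("list", spec@nReps)
  for (r in seq_len(spec@nReps)) {
    pr <- params$reps[[r]]
    bcF <- vector("list", length(pr$F))
    for (i in seq_along(pr$F)) {
      st <- encBlockFwd(XF, pr$F[[i]], fs@nHeads)
      XF <- st$out; bcF[[i]] <- st$cache
    }
    bcC <- vector("list", length(pr$C))
    for (i in seq_along(pr$C)) {
      st <- encBlockFwd(XC, pr$C[[i]], cs@nHeads)
      XC <- st$out; bcC[[i]] <- st$cache
    }
    fF <- fuseDirFwd(XF[1L, ], XC[-1L, , drop = FALSE], pr$fuse$F, cs@nHeads)
    fC <- fuseDirFwd(XC[1L, ], XF[-1L, , drop = FALSE], pr$fuse$C, fs@nHeads)
    XF[1L, ] <- fF$cls
    XC[1L, ] <- fC$cls
    repCaches[[r]] <- list(blocksF = bcF, blocksC = bcC,
                           fuseF = fF$cache, fuseC = fC$cache,
                           attnF = fF$attention, attnC = fC$attention)
  }
  hookF <- XF; hookC <- XC   # pre-final-LN state: Grad-CAM hook point
  lnF <- lnFwd(XF, params$finalLN$F$gamma, params$finalLN$F$beta)
  lnC <- lnFwd(XC, params$finalLN$C$gamma, params$finalLN$C$beta)
  list(F = lnF$Y, C = lnC$Y,
       cache = list(embF = embF, embC = embC, reps = repCaches,
                    lnF = lnF, lnC = lnC, hookF = hookF, hookC = hookC,
                    spec = spec, params = params))
}

## backward from gradients on the post-final-LN token matrices; also
## returns the gradients at the pre-final-LN hook point
ctBwd <- function(dF, dC, cache) {
  spec <- cache$spec; params <- cache$params
  gr <- treeZero(params)
  lfb <- lnBwd(dF, cache$lnF)
  lcb <- lnBwd(dC, cache$lnC)
  gr$finalLN$F$gamma <- lfb$dgamma; gr$finalLN$F$beta <- lfb$dbeta
  gr$finalLN$C$gamma <- lcb$dgamma; gr$finalLN$C$beta <- lcb$dbeta
  dXF <- lfb$dX; dXC <- lcb$dX
  dHookF <- dXF; dHookC <- dXC
  for (r in rev(seq_len(spec@nReps))) {
    rc <- cache$reps[[r]]
    ## un-fuse: both directions read the same pre-fusion state
    dClsF <- dXF[1L, ]; dClsC <- dXC[1L, ]
    dXF[1L, ] <- 0; dXC[1L, ] <- 0
    bF <- fuseDirBwd(dClsF, rc$fuseF)
    bC <- fuseDirBwd(dClsC, rc$fuseC)
    gr$reps[[r]]$fuse$F <- bF$grads
    gr$reps[[r]]$fuse$C <- bC$grads
    dXF[1L, ] <- dXF[1L, ] + bF$dClsOwn
    dXC[-1L, ] <- dXC[-1L, , drop = FALSE] + bF$dPatchesOther
    dXC[1L, ] <- dXC[1L, ] + bC$dClsOwn
    dXF[-1L, ] <- dXF[-1L, , drop = FALSE] + bC$dPatchesOther
    for (i in rev(seq_along(rc$blocksC))) {
      bb <- encBlockBwd(dXC, rc$blocksC[[i]])
      dXC <- bb$dX
      gr$reps[[r]]$C[[i]] <- bb$grads
    }
    for (i in rev(seq_along(rc$blocksF))) {
      bb <- encBlockBwd(dXF, rc$blocksF[[i]])
      dXF <- bb$dX
      gr$reps[[r]]$F[[i]] <- bb$grads
    }
  }
  ## patch embedding: tokens = rbind(cls, P W + b) + pos
  gr$embedF$pos <- dXF
  gr$embedF$cls <- dXF[1L, ]
  gr$embedF$W <- crossprod(cache$embF$patches, dXF[-1L, , drop = FALSE])
  gr$embedF$b <- colSums(dXF[-1L, , drop = FALSE])
  gr$embedC$pos <- dXC
  gr$embedC$cls <- dXC[1L, ]
  gr$embedC$W <- crossprod(cache$embC$patches, dXC[-1L, , drop = FALSE])
  gr$embedC$b <- colSums(dXC[-1L, , drop = FALSE])
  list(grads = gr, dHookF = dHookF, dHookC = dHookC)
}

#' Cross-scale backbone forward pass
#'
#' Embeds the image in both branches, runs the per-branch encoder stacks
#' and the cross-scale fusion \code{nReps} times, and applies the final
#' per-branch layer normalization.
#'
#' @param model a \code{\link{MILCTModel}} (see \code{\link{buildModel}}).
#' @param img raw image array; it is resized to each branch's input size
#'   internally.
#' @return list with \code{F} and \code{C}, the final token matrices
#'   (classification token in row 1), and \code{attention}, the fusion
#'   attention maps of the last repetition (or NULL when \code{nReps} is 0).
#' @export
ctForward <- function(model, img) {
  stopifnot(is(model, "MILCTModel"))
  f <- ctFwd(img, model@spec, model@params$backbone)
  nr <- model@spec@nReps
  att <- if (nr > 0L) list(F = f$cache$reps[[nr]]$attnF,
                           C = f$cache$reps[[nr]]$attnC) else NULL
  list(F = list(tokens = f$F, nPatches = nrow(f$F) - 1L),
       C = list(tokens = f$C, nPatches = nrow(f$C) - 1L),
       attention = att)
}
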