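test_that("patchEmbed produces the forced token counts", {
  set.seed(1)
  imgC <- randomImage(224L)
  seqC <- patchEmbed(imgC, BranchSpec(16L, 224L, 8L, nHeads = 2L))
  expect_equal(seqC$nPatches, 196L)
  expect_equal(nrow(seqC$tokens), 197L)

  seqF <- patchEmbed(randomImage(240L), BranchSpec(12L, 240L, 8L, nHeads = 2L))
  expect_equal(seqF$nPatches, 400L)
  expect_equal(nrow(seqF$tokens), 401L)

  expect_error(BranchSpec(12L, 230L, 8L), "divisible")
})

test_that("patchEmbed is linear in its parameters", {
  spec <- BranchSpec(8L, 16L, 6L, nHeads = 2L)
  params <- list(W = matrix(0, 3 * 64, 6), b = numeric(6),
                 cls = c(1, 2, 3, 4, 5, 6), pos = matrix(0, 5, 6))
  sq <- patchEmbed(array(0, c(16, 16, 3)), spec, params)
  ## zero weights, zero bias: patch tokens reflect only the -1 shift of the
  ## input normalization times zero weight = 0; cls equals its init
  expect_equal(sq$tokens[1, ], params$cls)
  expect_true(all(sq$tokens[-1, ] == 0))
})

test_that("layerNorm matches its defining formula", {
  expect_equal(layerNorm(c(5, 5, 5, 5)), rep(0, 4), tolerance = 1e-3)
  expect_equal(layerNorm(c(1, 2, 3), gamma = rep(0, 3), beta = c(7, 8, 9)),
               c(7, 8, 9))
  set.seed(2)
  x <- rnorm(4); g <- rnorm(4); b <- rnorm(4)
  expect_equal(layerNorm(x, g, b), lnOracle(x, g, b), tolerance = 1e-12)
})

test_that("mhsa satisfies the softmax-attention contracts", {
  set.seed(3)
  w <- milct:::initAttention(4L)
  one <- matrix(rnorm(4), 1, 4)
  r1 <- mhsa(one, w, nHeads = 2L)
  for (A in r1$attention) expect_equal(as.vector(A), 1)

  same <- matrix(rep(rnorm(4), each = 5), 5, 4)
  r2 <- mhsa(same, w, nHeads = 2L)
  for (A in r2$attention)
    expect_true(all(abs(A - 1 / 5) < 1e-12))

  expect_error(mhsa(one, w, nHeads = 3L), "divisible")

  rnd <- matrix(rnorm(6 * 4), 6, 4)
  r3 <- mhsa(rnd, w, nHeads = 2L)
  for (A in r3$attention)
    expect_equal(rowSums(A), rep(1, 6), tolerance = 1e-6)
})

test_that("mhsa matches a brute-force single-head oracle on two tokens", {
  X <- matrix(c(0.5, -0.3, 0.2, 0.8), 2, 2, byrow = TRUE)
  w <- list(Wq = matrix(c(0.1, -0.2, 0.3, 0.4), 2), bq = c(0.05, -0.05),
            Wk = matrix(c(0.2, 0.1, -0.1, 0.3), 2), bk = c(0, 0.1),
            Wv = matrix(c(0.3, 0.2, 0.1, -0.3), 2), bv = c(0.2, 0),
            Wo = matrix(c(1, 0.5, -0.5, 1), 2), bo = c(0.1, 0.2))
  out <- mhsa(X, w, nHeads = 1L)

  ## oracle: every matrix product written out explicitly
  Q <- X %*% w$Wq + rep(1, 2) %o% w$bq
  K <- X %*% w$Wk + rep(1, 2) %o% w$bk
  V <- X %*% w$Wv + rep(1, 2) %o% w$bv
  S <- Q %*% t(K) / sqrt(2)
  A <- t(apply(S, 1, softmaxOracle))
  expected <- (A %*% V) %*% w$Wo + rep(1, 2) %o% w$bo
  expect_equal(out$out, expected, tolerance = 1e-12)
  expect_equal(out$attention[[1]], A, tolerance = 1e-12)
})

test_that("encoderBlock is the identity when residual outputs are zeroed", {
  set.seed(4)
  p <- milct:::initBlockParams(6L, 2L)
  p$attn$Wo <- matrix(0, 6, 6); p$attn$bo <- numeric(6)
  p$ffn$W2 <- matrix(0, 12, 6); p$ffn$b2 <- numeric(6)
  X <- matrix(rnorm(5 * 6), 5, 6)
  expect_equal(encoderBlock(X, p, nHeads = 2L), X, tolerance = 1e-12)
})

test_that("encoderBlock equals the composition of its sub-operations", {
  set.seed(5)
  p <- milct:::initBlockParams(4L, 2L)
  X <- matrix(rnorm(3 * 4), 3, 4)
  out <- encoderBlock(X, p, nHeads = 2L)
  expect_equal(dim(out), dim(X))

  ln1 <- t(apply(X, 1, lnOracle, gamma = p$ln1$gamma, beta = p$ln1$beta))
  y <- X + mhsa(ln1, p$attn, nHeads = 2L)$out
  ln2 <- t(apply(y, 1, lnOracle, gamma = p$ln2$gamma, beta = p$ln2$beta))
  H1 <- ln2 %*% p$ffn$W1 + rep(1, 3) %o% p$ffn$b1
  G <- H1 * pnorm(H1)
  expected <- y + G %*% p$ffn$W2 + rep(1, 3) %o% p$ffn$b2
  expect_equal(out, expected, tolerance = 1e-12)
})

test_that("cross-scale fusion leaves patch tokens bitwise unchanged and
           uses a single-row attention map", {
  set.seed(6)
  fparams <- list(F = milct:::initFuseParams(4L, 6L),
                  C = milct:::initFuseParams(6L, 4L))
  seqF <- list(tokens = matrix(rnorm(5 * 4), 5, 4))
  seqC <- list(tokens = matrix(rnorm(8 * 6), 8, 6))
  out <- crossAttentionFuse(seqF, seqC, fparams, nHeadsF = 2L, nHeadsC = 2L)

  expect_identical(out$F$tokens[-1, ], seqF$tokens[-1, ])
  expect_identical(out$C$tokens[-1, ], seqC$tokens[-1, ])
  expect_false(identical(out$F$tokens[1, ], seqF$tokens[1, ]))
  for (A in out$F$attention) {
    expect_equal(nrow(A), 1L)          # linear complexity: one query row
    expect_equal(ncol(A), 8L)          # projected cls + 7 patches of C
    expect_equal(rowSums(A), 1, tolerance = 1e-6)
  }
  for (A in out$C$attention) expect_equal(dim(A), c(1L, 5L))
})

test_that("cross-scale fusion matches a step-by-step oracle", {
  set.seed(7)
  fparams <- list(F = milct:::initFuseParams(2L, 2L),
                  C = milct:::initFuseParams(2L, 2L))
  seqF <- list(tokens = matrix(rnorm(2 * 2), 2, 2))  # cls + 1 patch
  seqC <- list(tokens = matrix(rnorm(2 * 2), 2, 2))
  out <- crossAttentionFuse(seqF, seqC, fparams, nHeadsF = 1L, nHeadsC = 1L)

  ## oracle for the direction updating the F cls over C's patches
  p <- fparams$F
  pc <- lnOracle(seqF$tokens[1, ], p$lnP$gamma, p$lnP$beta) %*% p$proj$W +
    p$proj$b
  xhat <- rbind(pc, seqC$tokens[-1, , drop = FALSE])
  xn <- t(apply(xhat, 1, lnOracle, gamma = p$lnX$gamma, beta = p$lnX$beta))
  Q <- xn[1, , drop = FALSE] %*% p$attn$Wq + p$attn$bq
  K <- xn %*% p$attn$Wk + rep(1, 2) %o% p$attn$bk
  V <- xn %*% p$attn$Wv + rep(1, 2) %o% p$attn$bv
  A <- softmaxOracle(as.vector(Q %*% t(K)) / sqrt(2))
  att <- (matrix(A, 1) %*% V) %*% p$attn$Wo + p$attn$bo
  u <- pc + att
  z <- lnOracle(as.vector(u), p$lnB$gamma, p$lnB$beta) %*% p$back$W +
    p$back$b
  expect_equal(out$F$tokens[1, ], as.vector(z), tolerance = 1e-10)
})

test_that("fusion degenerates gracefully when the other branch has no
           patch tokens", {
  set.seed(8)
  fparams <- list(F = milct:::initFuseParams(4L, 4L),
                  C = milct:::initFuseParams(4L, 4L))
  seqF <- list(tokens = matrix(rnorm(4), 1, 4))  # cls only
  seqC <- list(tokens = matrix(rnorm(4), 1, 4))
  out <- crossAttentionFuse(seqF, seqC, fparams, 2L, 2L)
  for (A in out$F$attention) expect_equal(as.vector(A), 1)  # self only
  expect_equal(dim(out$F$tokens), c(1L, 4L))
})

test_that("ctForward produces the shapes forced by the specs", {
  spec <- tinyModelSpec()
  model <- buildModel(spec, MILHeadSpec(8L, 4L), seed = 10)
  out <- ctForward(model, randomImage(96L, seed = 1))
  expect_equal(dim(out$F$tokens), c(65L, 32L))   # (96/12)^2 + 1 tokens
  expect_equal(dim(out$C$tokens), c(37L, 64L))   # (96/16)^2 + 1 tokens
  expect_equal(length(out$attention$F), spec@cBranch@nHeads)
})

test_that("ctForward with zero repetitions is the normalized embedding", {
  spec <- ModelSpec(BranchSpec(8L, 16L, 6L, nHeads = 2L),
                    BranchSpec(16L, 16L, 8L, nHeads = 2L), nReps = 0L)
  model <- buildModel(spec, MILHeadSpec(4L, 3L), seed = 11)
  img <- randomImage(16L, seed = 2)
  out <- ctForward(model, img)
  emb <- patchEmbed(img, spec@fBranch, model@params$backbone$embedF)
  fin <- model@params$backbone$finalLN$F
  expected <- t(apply(emb$tokens, 1, lnOracle, gamma = fin$gamma,
                      beta = fin$beta))
  expect_equal(out$F$tokens, expected, tolerance = 1e-10)
  expect_null(out$attention)
})

test_that("ctForward is deterministic and symmetric under tied branches", {
  spec <- ModelSpec(BranchSpec(8L, 16L, 6L, depth = 1L, nHeads = 2L),
                    BranchSpec(8L, 16L, 6L, depth = 1L, nHeads = 2L),
                    nReps = 2L)
  model <- buildModel(spec, MILHeadSpec(4L, 3L), seed = 12)
  ## tie the two branches' weights
  bp <- model@params$backbone
  bp$embedC <- bp$embedF
  for (r in seq_len(spec@nReps)) {
    bp$reps[[r]]$C <- bp$reps[[r]]$F
    bp$reps[[r]]$fuse$C <- bp$reps[[r]]$fuse$F
  }
  bp$finalLN$C <- bp$finalLN$F
  model@params$backbone <- bp
  img <- randomImage(16L, seed = 3)
  out1 <- ctForward(model, img)
  out2 <- ctForward(model, img)
  expect_identical(out1$F$tokens, out2$F$tokens)   # determinism
  expect_equal(out1$F$tokens, out1$C$tokens, tolerance = 1e-12)
})

test_that("backbone gradients w.r.t. the embedding weights match finite
           differences", {
  model <- buildModel(gradSpec(), gradMilSpec(), seed = 13)
  img <- randomImage(24L, seed = 4)
  y <- c(0, 1)
  lossOf <- function(m) {
    f <- milct:::milctFwd(m, img)
    milct:::milctLossAndGrad(m, f, y)$loss
  }
  fwd <- milct:::milctFwd(model, img)
  lg <- milct:::milctLossAndGrad(model, fwd, y)
  bw <- milct:::milctBwd(model, fwd, lg$dLogits)
  eps <- 1e-5
  set.seed(14)
  for (branch in c("embedF", "embedC")) {
    checked <- 0L
    while (checked < 3L) {
      i <- sample(length(model@params$backbone[[branch]]$W), 1)
      ana <- bw$grads$backbone[[branch]]$W[i]
      if (abs(ana) < 1e-6) next
      m1 <- model; m1@params$backbone[[branch]]$W[i] <-
        m1@params$backbone[[branch]]$W[i] + eps
      m2 <- model; m2@params$backbone[[branch]]$W[i] <-
        m2@params$backbone[[branch]]$W[i] - eps
      num <- (lossOf(m1) - lossOf(m2)) / (2 * eps)
      expect_equal(ana, num, tolerance = 1e-3)
      checked <- checked + 1L
    }
    ## the embedding receives usable gradient at all
    expect_gt(sqrt(sum(bw$grads$backbone[[branch]]$W^2)), 0)
  }
})
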