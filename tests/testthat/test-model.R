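test_that("parameter counting is exact and monotone", {
  ## a single linear map with bias: in*out + out entries
  expect_equal(milct:::paramCountTree(list(W = matrix(0, 4, 3),
                                           b = numeric(3))), 15)

  spec <- gradSpec()
  model <- buildModel(spec, gradMilSpec(), seed = 31)
  total <- parameterCount(model)
  ## equals the sum over independently counted submodules
  expect_equal(total,
               milct:::paramCountTree(model@params$backbone) +
               milct:::paramCountTree(model@params$mlp) +
               milct:::paramCountTree(model@params$mil))

  wider <- ModelSpec(spec@fBranch,
                     BranchSpec(12L, 24L, 24L, depth = 2L, nHeads = 2L,
                                ffnExpansion = 2L),
                     nReps = spec@nReps, eta = spec@eta)
  expect_gt(parameterCount(buildModel(wider, gradMilSpec(), seed = 31)),
            total)

  expect_error(buildModel(spec, MILHeadSpec(4L, 3L, nClasses = 3L)),
               "disagree")
})

test_that("jointLoss follows its defining arithmetic", {
  ## perfectly confident, correct classification-token head, eta = 1
  expect_equal(jointLoss(c(1, 0), c(1, 0), c(0.5, 0.5), eta = 1), 0)

  ## equal heads at eta = 0.5 collapse to plain cross-entropy
  p <- c(0.3, 0.7)
  expect_equal(jointLoss(c(0, 1), p, p, eta = 0.5), -log(0.7))

  ## hand-computed mixed case (one branch)
  expect_equal(jointLoss(c(1, 0), c(0.7, 0.3), c(0.6, 0.4), eta = 0.6),
               -0.6 * log(0.7) - 0.4 * log(0.6), tolerance = 1e-12)
  expect_equal(-0.6 * log(0.7) - 0.4 * log(0.6), 0.41834, tolerance = 1e-4)

  ## two identical branches double the loss
  expect_equal(jointLoss(c(1, 0), list(c(0.7, 0.3), c(0.7, 0.3)),
                         list(c(0.6, 0.4), c(0.6, 0.4)), eta = 0.6),
               2 * (-0.6 * log(0.7) - 0.4 * log(0.6)), tolerance = 1e-12)

  expect_error(jointLoss(c(1, 0), c(0.7, 0.4), c(0.6, 0.4)), "sum to 1")
  expect_error(jointLoss(c(1, 0), c(1.2, -0.2), c(0.6, 0.4)), "in \\[0,1\\]")
  expect_error(jointLoss(c(1, 0), c(0.7, 0.3), c(0.6, 0.4), eta = 1.5),
               "eta")
})

test_that("jointLoss is non-negative and decreasing in the true-class
           probability of either head", {
  ps <- seq(0.05, 0.95, by = 0.1)
  lossesMlp <- vapply(ps, function(p)
    jointLoss(c(1, 0), c(p, 1 - p), c(0.5, 0.5), eta = 0.6), numeric(1))
  lossesMil <- vapply(ps, function(p)
    jointLoss(c(1, 0), c(0.5, 0.5), c(p, 1 - p), eta = 0.6), numeric(1))
  expect_true(all(lossesMlp > 0))
  expect_true(all(diff(lossesMlp) < 0))
  expect_true(all(diff(lossesMil) < 0))
})

test_that("eta = 1 zeroes the bag-head gradients and eta = 0 the
           classification-token gradients", {
  img <- randomImage(24L, seed = 32)
  y <- c(0, 1)
  for (eta in c(1, 0)) {
    spec <- gradSpec(); spec@eta <- eta
    model <- buildModel(spec, gradMilSpec(), seed = 33)
    fwd <- milct:::milctFwd(model, img)
    lg <- milct:::milctLossAndGrad(model, fwd, y)
    bw <- milct:::milctBwd(model, fwd, lg$dLogits)
    milNorm <- sqrt(sum(unlist(bw$grads$mil)^2))
    mlpNorm <- sqrt(sum(unlist(bw$grads$mlp)^2))
    if (eta == 1) {
      expect_equal(milNorm, 0)
      expect_gt(mlpNorm, 0)
    } else {
      expect_equal(mlpNorm, 0)
      expect_gt(milNorm, 0)
    }
  }
})

test_that("one optimizer step without weight decay leaves the zero-gradient
           head untouched", {
  set.seed(34)
  samples <- list(list(image = randomImage(24L), label = 0L),
                  list(image = randomImage(24L), label = 1L))
  spec <- gradSpec(); spec@eta <- 1
  model <- buildModel(spec, gradMilSpec(), seed = 35)
  before <- model@params$mil
  fit <- trainMILCT(samples, model = model, epochs = 1L, batchSize = 2L,
                    weightDecay = 0, seed = 36)
  expect_identical(fit$model@params$mil, before)
  expect_false(identical(fit$model@params$mlp, model@params$mlp))
})

test_that("the full model gradient matches finite differences on random
           coordinates", {
  model <- buildModel(gradSpec(), gradMilSpec(), seed = 37)
  img <- randomImage(24L, seed = 38)
  y <- c(1, 0)
  lossOf <- function(m) {
    f <- milct:::milctFwd(m, img)
    milct:::milctLossAndGrad(m, f, y)$loss
  }
  fwd <- milct:::milctFwd(model, img)
  lg <- milct:::milctLossAndGrad(model, fwd, y)
  bw <- milct:::milctBwd(model, fwd, lg$dLogits)
  leaves <- paramLeaves(model@params)
  eps <- 1e-5
  set.seed(39)
  checked <- 0L
  while (checked < 25L) {
    leaf <- leaves[[sample(length(leaves), 1)]]
    ci <- sample(leaf$len, 1)
    ana <- leafGet(bw$grads, leaf$path)[ci]
    if (abs(ana) < 1e-6) next
    m1 <- model
    v <- leafGet(m1@params, leaf$path); v[ci] <- v[ci] + eps
    m1@params <- leafSet(m1@params, leaf$path, v)
    m2 <- model
    v <- leafGet(m2@params, leaf$path); v[ci] <- v[ci] - eps
    m2@params <- leafSet(m2@params, leaf$path, v)
    num <- (lossOf(m1) - lossOf(m2)) / (2 * eps)
    expect_equal(ana, num, tolerance = 5e-3)
    checked <- checked + 1L
  }
})

test_that("predictFused returns a normalized mixture of the four heads", {
  model <- buildModel(gradSpec(), gradMilSpec(), seed = 40)
  img <- randomImage(24L, seed = 41)
  pr <- predictFused(model, img)
  expect_equal(sum(pr$yFused), 1, tolerance = 1e-9)
  expect_true(all(pr$yFused >= 0))
  expect_true(pr$yHat %in% c(0L, 1L))

  ## matches the explicit weighted-average oracle on the head outputs
  eta <- model@spec@eta
  manual <- eta * (pr$yMlp$C + pr$yMlp$F) / 2 +
    (1 - eta) * (pr$yMil$C + pr$yMil$F) / 2
  expect_equal(pr$yFused, manual / sum(manual), tolerance = 1e-12)

  ## when all four heads agree the fusion is that shared vector
  p <- c(0.82, 0.18)
  expect_equal(milct:::fusedProb(list(mlpC = p, mlpF = p, milC = p,
                                      milF = p), eta = 0.3), p)

  ## branch order cannot matter: swapping branch labels in the average
  swapped <- eta * (pr$yMlp$F + pr$yMlp$C) / 2 +
    (1 - eta) * (pr$yMil$F + pr$yMil$C) / 2
  expect_equal(pr$yFused, swapped / sum(swapped), tolerance = 1e-12)
})

test_that("checkpoints and flat config files round-trip", {
  dir <- withr::local_tempdir()
  model <- buildModel(gradSpec(), gradMilSpec(), seed = 42)
  ck <- file.path(dir, "model.rds")
  saveMILCT(model, ck)
  back <- loadMILCT(ck)
  expect_identical(back@params, model@params)
  img <- randomImage(24L, seed = 43)
  expect_identical(predictFused(back, img)$yFused,
                   predictFused(model, img)$yFused)

  cfgPath <- file.path(dir, "model.cfg")
  writeModelConfig(model@spec, model@milSpec, cfgPath)
  cfg <- readModelConfig(cfgPath)
  expect_equal(cfg$spec, model@spec)
  expect_equal(cfg$milSpec, model@milSpec)
})
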