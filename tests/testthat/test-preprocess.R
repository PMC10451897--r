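test_that("removeBorders crops to the informative region", {
  expect_error(removeBorders(array(0, c(100, 100, 3))), "unusable")

  one <- array(0, c(50, 60, 3))
  one[10, 20, 2] <- 200
  crop <- removeBorders(one, 10)
  expect_equal(dim(crop), c(1L, 1L, 3L))
  expect_equal(crop[1, 1, 2], 200)

  ## bright disc on black canvas: bounding box must match a brute-force
  ## scan over all above-threshold rows and columns
  img <- array(0, c(128, 128, 3))
  for (i in 1:128) for (j in 1:128)
    if ((i - 64)^2 + (j - 64)^2 <= 40^2) img[i, j, ] <- c(180, 120, 60)
  crop <- removeBorders(img, 10)
  fg <- apply(img, c(1, 2), max) > 10
  rows <- range(which(apply(fg, 1, any)))
  cols <- range(which(apply(fg, 2, any)))
  expect_equal(dim(crop)[1:2], c(diff(rows) + 1L, diff(cols) + 1L))
  expect_equal(crop, img[rows[1]:rows[2], cols[1]:cols[2], , drop = FALSE])
})

test_that("removeBorders is idempotent and keeps every foreground pixel", {
  set.seed(71)
  for (rep in 1:10) {
    img <- array(0, c(40, 40, 3))
    npix <- sample(1:8, 1)
    for (k in seq_len(npix)) {
      img[sample(5:35, 1), sample(5:35, 1), sample(1:3, 1)] <-
        runif(1, 20, 255)
    }
    crop <- removeBorders(img, 10)
    expect_identical(removeBorders(crop, 10), crop)
    ## no above-threshold pixel may be lost
    expect_equal(sum(apply(crop, c(1, 2), max) > 10),
                 sum(apply(img, c(1, 2), max) > 10))
  }
})

test_that("claheEnhance maps a constant image to a constant image", {
  img <- array(77, c(24, 24, 3))
  out <- claheEnhance(img, clipLimit = 7, tileGrid = 3L)
  expect_equal(dim(out), dim(img))
  expect_true(all(abs(out - out[1, 1, 1]) < 1e-9))
  expect_true(min(out) >= 0 && max(out) <= 255)
})

test_that("single-tile CLAHE is monotone along an intensity gradient", {
  w <- 64
  img <- array(rep(seq(30, 220, length.out = w), each = 32), c(32, w, 3))
  out <- claheEnhance(img, clipLimit = 1000, tileGrid = 1L)
  lum <- out[16, , 1]
  expect_true(all(diff(lum) >= -1e-9))
})

test_that("single-tile CLAHE with a large clip limit equals plain histogram
           equalization", {
  ## two-level 8x8 grayscale image; oracle: lut(v) = round(cdf(v)*255/n)
  v <- matrix(50, 8, 8)
  v[1:4, ] <- 200
  img <- array(rep(v, 3), c(8, 8, 3))
  out <- claheEnhance(img, clipLimit = 1e6, tileGrid = 1L)
  counts <- tabulate(as.vector(v) + 1L, nbins = 256L)
  lut <- round(cumsum(counts) * 255 / 64)
  expected <- matrix(lut[v + 1L], 8, 8)
  expect_equal(out[, , 1], expected, tolerance = 1e-8)
  expect_equal(out[, , 2], expected, tolerance = 1e-8)
})

test_that("claheEnhance rejects a grid finer than the image", {
  expect_error(claheEnhance(array(10, c(4, 4, 3)), tileGrid = 8L),
               "finer than the image")
})

test_that("gaussianEnhance follows its defining formula in degenerate cases", {
  img <- array(runif(20 * 20 * 3, 0, 255), c(20, 20, 3))
  out0 <- gaussianEnhance(img, kappa = 0, sigma = 2, delta = 128)
  expect_true(all(abs(out0 - 128) < 1e-9))

  flat <- array(99, c(16, 16, 3))
  outF <- gaussianEnhance(flat, kappa = 4, sigma = 2, delta = 128)
  expect_true(all(abs(outF - 128) < 1e-6))

  expect_error(gaussianEnhance(img, kappa = NA, sigma = 2), "finite")
  expect_error(gaussianEnhance(img, kappa = 4, sigma = 0), "sigma")
})

test_that("gaussianEnhance matches an explicit convolution oracle on a
           single bright pixel", {
  s <- 31L
  img <- array(0, c(s, s, 3))
  img[16, 16, ] <- 200
  sigma <- 1.2
  kappa <- 3; delta <- 100
  out <- gaussianEnhance(img, kappa = kappa, sigma = sigma, delta = delta)

  ## oracle: direct convolution with the truncated sampled Gaussian
  radius <- ceiling(3 * sigma)
  d <- (-radius):radius
  k <- outer(exp(-d^2 / (2 * sigma^2)), exp(-d^2 / (2 * sigma^2)))
  k <- k / sum(k)
  blurCenter <- 200 * k[radius + 1, radius + 1]
  expected <- kappa * (200 - blurCenter) + delta
  expect_equal(out[16, 16, 1], min(max(expected, 0), 255), tolerance = 1e-4)

  ## an off-centre position inside the kernel support
  blurOff <- 200 * k[radius + 1 + 1, radius + 1]
  expectedOff <- kappa * (0 - blurOff) + delta
  expect_equal(out[17, 16, 1], min(max(expectedOff, 0), 255),
               tolerance = 1e-4)
})

test_that("gaussianEnhance commutes with horizontal flip", {
  set.seed(5)
  img <- array(runif(24 * 30 * 3, 0, 255), c(24, 30, 3))
  flip <- function(x) x[, dim(x)[2]:1, , drop = FALSE]
  a <- gaussianEnhance(flip(img), kappa = 4, sigma = 1.5, delta = 128)
  b <- flip(gaussianEnhance(img, kappa = 4, sigma = 1.5, delta = 128))
  expect_equal(a, b, tolerance = 1e-8)
})

test_that("preprocessImage preserves the range contract", {
  set.seed(8)
  img <- array(0, c(60, 60, 3))
  img[10:50, 10:50, ] <- runif(41 * 41 * 3, 30, 220)
  out <- preprocessImage(img, PreprocessConfig(tileGrid = 3L))
  expect_equal(length(dim(out)), 3L)
  expect_true(min(out) >= 0 && max(out) <= 255)
  expect_equal(dim(out)[1:2], c(41L, 41L))   # border removal happened
})

makeSamples <- function(n0, n1, s = 20L) {
  set.seed(99)
  c(lapply(seq_len(n0), function(i)
      list(image = array(runif(s * s * 3, 0, 255), c(s, s, 3)), label = 0L)),
    lapply(seq_len(n1), function(i)
      list(image = array(runif(s * s * 3, 0, 255), c(s, s, 3)), label = 1L)))
}

test_that("augmentMinority balances classes and keeps the originals", {
  samples <- makeSamples(10L, 5L)
  out <- augmentMinority(samples, seed = 4L)
  labs <- vapply(out, function(s) s$label, integer(1))
  expect_equal(as.integer(table(labs)), c(10L, 10L))
  ## originals untouched, in place
  for (i in seq_along(samples)) expect_identical(out[[i]], samples[[i]])
  ## added samples are flagged and from the minority class
  added <- out[(length(samples) + 1L):length(out)]
  expect_true(all(vapply(added, function(s) isTRUE(s$augmented), logical(1))))
  expect_true(all(vapply(added, function(s) s$label, integer(1)) == 1L))
})

test_that("augmentMinority is deterministic and rejects degenerate input", {
  samples <- makeSamples(6L, 3L)
  a <- augmentMinority(samples, seed = 12L)
  b <- augmentMinority(samples, seed = 12L)
  expect_identical(a, b)

  balanced <- makeSamples(4L, 4L)
  expect_identical(augmentMinority(balanced, seed = 1L), balanced)

  oneClass <- makeSamples(5L, 0L)
  expect_error(augmentMinority(oneClass, seed = 1L), "both classes")

  out <- augmentMinority(samples, seed = 3L)
  rng <- range(vapply(out, function(s) range(s$image), numeric(2)))
  expect_true(rng[1] >= 0 && rng[2] <= 255)
})
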