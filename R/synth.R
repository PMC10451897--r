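## Deterministic two-class synthetic fundus generator.  Images are an
## orange-tinted circular disc on black background with dark curvilinear
## vessels (random quadratic Bezier curves growing from the disc centre
## region outward).  Positive-class images additionally carry a bright
## central reflex stripe along a labelled "arterial" subset of vessels,
## emulating the widened bright reflective band of the enhanced arterial
## light reflex.  All geometry is drawn from the random stream before any
## class-dependent rendering, so a class-0 and class-1 image generated
## from the same seeds share identical vessels and differ only by the
## stripes.

quadBezier <- function(p0, p1, p2, n = 80L) {
  t <- seq(0, 1, length.out = n)
  cbind((1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1],
        (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2])
}

## per-pixel distance to a sampled centerline, restricted to a bounding box
centerlineDistance <- function(pts, radius, S) {
  rmin <- max(1L, floor(min(pts[, 1]) - radius - 2))
  rmax <- min(S, ceiling(max(pts[, 1]) + radius + 2))
  cmin <- max(1L, floor(min(pts[, 2]) - radius - 2))
  cmax <- min(S, ceiling(max(pts[, 2]) + radius + 2))
  ys <- rep(rmin:rmax, times = cmax - cmin + 1L)
  xs <- rep(cmin:cmax, each = rmax - rmin + 1L)
  minD2 <- rep(Inf, length(ys))
  for (k in seq_len(nrow(pts)))
    minD2 <- pmin(minD2, (ys - pts[k, 1])^2 + (xs - pts[k, 2])^2)
  list(rows = ys, cols = xs, dist = sqrt(minD2))
}

#' Generate one synthetic fundus image
#'
#' @param cls class label: 0 (no reflex stripes) or 1 (bright reflex
#'   stripes along the arterial vessel subset).
#' @param cfg a \code{\link{SynthConfig}}.
#' @param sampleSeed per-sample seed; together with \code{cfg@seed} it
#'   fully determines the image.
#' @return a sample: list with \code{image} (raw image array),
#'   \code{label}, \code{seed}, and \code{meta} holding the generator's
#'   own geometry (vessel centerlines as (row, col) matrices, widths, the
#'   arterial subset, the disc bounding box and centre).
#' @export
generateFundusSample <- function(cls, cfg = SynthConfig(), sampleSeed = 1L) {
  stopifnot(is(cfg, "SynthConfig"))
  if (!cls %in% c(0L, 1L)) stop("cls must be 0 or 1")
  set.seed((cfg@seed %% 100000L) * 20011L + (as.integer(sampleSeed) %% 20000L))

  S <- cfg@imageSize
  ctr <- (S + 1) / 2
  R <- 0.46 * S
  ii <- rep(seq_len(S), times = S)
  jj <- rep(seq_len(S), each = S)
  d2 <- matrix((ii - ctr)^2 + (jj - ctr)^2, S, S)
  disc <- d2 <= R^2
  shade <- pmax(0.72 + 0.28 * (1 - d2 / R^2), 0)

  img <- array(0, c(S, S, 3L))
  baseCol <- c(205, 122, 62)
  for (ch in 1:3)
    img[, , ch] <- (baseCol[ch] * shade + matrix(rnorm(S * S, 0, 4), S, S)) * disc

  jitter <- runif(1, -15, 15)   # per-image brightness jitter, both classes

  ## vessel geometry (class-independent random stream)
  nv <- sample(cfg@nVessels[1]:cfg@nVessels[2], 1L)
  widths <- runif(nv, cfg@vesselWidth[1], cfg@vesselWidth[2])
  curves <- vector("list", nv)
  for (v in seq_len(nv)) {
    a0 <- runif(1, 0, 2 * pi)
    r0 <- runif(1, 0, 0.15 * R)
    p0 <- c(ctr + r0 * sin(a0), ctr + r0 * cos(a0))
    a1 <- a0 + runif(1, -0.9, 0.9)
    r1 <- runif(1, 0.72, 0.92) * R
    p2 <- c(ctr + r1 * sin(a1), ctr + r1 * cos(a1))
    mid <- (p0 + p2) / 2
    perp <- c(-(p2[2] - p0[2]), p2[1] - p0[1])
    perp <- perp / max(sqrt(sum(perp^2)), 1e-9)
    p1 <- mid + perp * runif(1, -0.22, 0.22) * R
    curves[[v]] <- quadBezier(p0, p1, p2, n = max(60L, S))
  }
  arterial <- sort(sample(nv, ceiling(nv / 2)))

  ## render vessels (dark) then, for class 1, the bright reflex stripes
  vesselCol <- c(96, 38, 30)
  stripeGain <- c(1, 0.8, 0.55)
  for (v in seq_len(nv)) {
    cd <- centerlineDistance(curves[[v]], widths[v] / 2 + 2, S)
    inside <- disc[cbind(cd$rows, cd$cols)]
    alpha <- pmin(1, pmax(0, (widths[v] / 2 + 0.7 - cd$dist) / 1.4)) * inside
    sel <- alpha > 0
    if (any(sel)) {
      pix <- cbind(cd$rows[sel], cd$cols[sel])
      a <- alpha[sel]
      for (ch in 1:3) {
        idx <- cbind(pix, ch)
        img[idx] <- img[idx] * (1 - a) + vesselCol[ch] * a
      }
    }
    if (cls == 1L && v %in% arterial) {
      sw <- max(0.5, cfg@reflexWidthFraction * widths[v] / 2)
      alphaS <- pmin(1, pmax(0, (sw + 0.5 - cd$dist) / 1.0)) * inside
      selS <- alphaS > 0
      if (any(selS)) {
        pixS <- cbind(cd$rows[selS], cd$cols[selS])
        aS <- alphaS[selS]
        for (ch in 1:3) {
          idx <- cbind(pixS, ch)
          img[idx] <- img[idx] + aS * cfg@reflexBrightness * stripeGain[ch]
        }
      }
    }
  }

  for (ch in 1:3) img[, , ch] <- (img[, , ch] + jitter) * disc
  img <- clip255(img)

  discRows <- range(which(rowSums(disc) > 0L))
  discCols <- range(which(colSums(disc) > 0L))
  list(image = img, label = as.integer(cls), seed = as.integer(sampleSeed),
       meta = list(centerlines = curves, widths = widths,
                   arterial = arterial,
                   discBBox = c(rowMin = discRows[1], rowMax = discRows[2],
                                colMin = discCols[1], colMax = discCols[2]),
                   center = c(ctr, ctr)))
}

#' Generate a balanced in-memory synthetic dataset
#'
#' \code{nPerClass} samples per class with distinct per-sample seeds
#' (class 0 uses seeds 1..n, class 1 seeds n+1..2n, so the two classes
#' have independent geometry).
#'
#' @param cfg a \code{\link{SynthConfig}}.
#' @return list of samples (see \code{\link{generateFundusSample}}).
#' @export
generateFundusSamples <- function(cfg = SynthConfig()) {
  n <- cfg@nPerClass
  out <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    out[[i]] <- generateFundusSample(0L, cfg, sampleSeed = i)
    out[[n + i]] <- generateFundusSample(1L, cfg, sampleSeed = n + i)
  }
  out
}

#' Generate a synthetic dataset on disk
#'
#' Writes \code{nPerClass} PNG images per class and a manifest CSV with
#' columns \code{path,label,seed} (paths relative to \code{outDir}).
#' Re-running with the same configuration reproduces identical files.
#'
#' @param cfg a \code{\link{SynthConfig}}.
#' @param outDir output directory (created if needed).
#' @return the manifest data frame, invisibly; the manifest is also
#'   written to \code{file.path(outDir, "manifest.csv")}.
#' @export
generateFundusDataset <- function(cfg = SynthConfig(), outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  n <- cfg@nPerClass
  rows <- vector("list", 2L * n)
  k <- 0L
  for (cls in c(0L, 1L)) for (i in seq_len(n)) {
    k <- k + 1L
    sampleSeed <- cls * n + i
    smp <- generateFundusSample(cls, cfg, sampleSeed = sampleSeed)
    fname <- sprintf("class%d_%04d.png", cls, i)
    writeFundusImage(smp$image, file.path(outDir, fname))
    rows[[k]] <- data.frame(path = fname, label = cls, seed = sampleSeed,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  writeManifest(manifest, file.path(outDir, "manifest.csv"))
  invisible(manifest)
}
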