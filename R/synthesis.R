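#' Generate a tissue-like phantom image
#'
#' Procedural stand-in for a stitched fluorescence image: smooth Gaussian
#' "cell" blobs and curvilinear "fiber" ridges over a flat background. Used
#' as the clean ground truth onto which stripe fields and artifacts are
#' applied. Deterministic given `seed`.
#'
#' With one channel, cells and fibers are summed; with two, channel 1 holds
#' cells and channel 2 fibers; with three, channel 3 additionally holds an
#' equal mixture — mimicking two-channel multiphoton pseudo-colour plus a
#' composite.
#'
#' @param seed integer seed.
#' @param size `(H, W)`, both >= 64.
#' @param nCells,nFibers structure counts (>= 0).
#' @param backgroundLevel flat background intensity in `[0, 1)`.
#' @param channels 1, 2 or 3.
#' @param nonOverlapping if TRUE, cells are placed so their thresholded
#'   supports cannot touch (rejection sampling); an error is raised if the
#'   image cannot host `nCells` such blobs.
#' @return an [ImageRaster-class] with values in `[0, 1]`.
#' @examples
#' ph <- generatePhantom(1, c(96, 96), nCells = 5, nFibers = 2)
#' @export
generatePhantom <- function(seed, size, nCells = 30, nFibers = 8,
                            backgroundLevel = 0.1, channels = 1,
                            nonOverlapping = FALSE) {
  H <- as.integer(size[1]); W <- as.integer(size[2])
  if (H < 64L || W < 64L) invalidArgument("phantom size must be at least 64 x 64")
  if (nCells < 0 || nFibers < 0) invalidArgument("structure counts must be >= 0")
  if (!channels %in% 1:3) invalidArgument("channels must be 1, 2 or 3")

  withSeed(seed, {
    cells <- matrix(0, H, W)
    if (nCells > 0) {
      rows <- seq_len(H) - 1L
      cols <- seq_len(W) - 1L
      placed <- matrix(numeric(0), 0, 3)  # (r, c, cutoff radius)
      tries <- 0L
      while (nrow(placed) < nCells) {
        tries <- tries + 1L
        if (tries > 200L * nCells)
          invalidArgument("could not place non-overlapping cells; reduce nCells")
        sigma <- runif(1, 2.0, 4.0)
        amp <- runif(1, 0.55, 1.0)
        # radius at which the blob falls below 0.05 (threshold margin)
        cut <- sigma * sqrt(2 * log(amp / 0.05))
        r <- runif(1, cut + 1, H - cut - 2)
        c <- runif(1, cut + 1, W - cut - 2)
        if (nonOverlapping && nrow(placed) > 0) {
          dd <- sqrt((placed[, 1] - r)^2 + (placed[, 2] - c)^2)
          if (any(dd < placed[, 3] + cut + 2)) next
        }
        placed <- rbind(placed, c(r, c, cut))
        cells <- cells + amp * exp(-(outer((rows - r)^2, (cols - c)^2, "+")) /
                                     (2 * sigma^2))
      }
    }
    fibers <- matrix(0, H, W)
    if (nFibers > 0) {
      for (f in seq_len(nFibers)) {
        # quadratic Bezier between random edge-ish points
        p0 <- c(runif(1, 0, H - 1), runif(1, 0, W - 1))
        p2 <- c(runif(1, 0, H - 1), runif(1, 0, W - 1))
        p1 <- (p0 + p2) / 2 + stats::rnorm(2, 0, max(H, W) / 6)
        amp <- runif(1, 0.3, 0.7)
        width <- runif(1, 0.8, 1.6)
        nSamp <- max(16L, as.integer(2 * sqrt(sum((p2 - p0)^2))))
        t <- seq(0, 1, length.out = nSamp)
        pr <- (1 - t)^2 * p0[1] + 2 * (1 - t) * t * p1[1] + t^2 * p2[1]
        pc <- (1 - t)^2 * p0[2] + 2 * (1 - t) * t * p1[2] + t^2 * p2[2]
        rad <- as.integer(ceiling(3 * width))
        for (s in seq_len(nSamp)) {
          r0 <- max(0L, as.integer(floor(pr[s])) - rad)
          r1 <- min(H - 1L, as.integer(ceiling(pr[s])) + rad)
          c0 <- max(0L, as.integer(floor(pc[s])) - rad)
          c1 <- min(W - 1L, as.integer(ceiling(pc[s])) + rad)
          if (r1 < r0 || c1 < c0) next
          rr <- r0:r1; cc <- c0:c1
          g <- amp * exp(-outer((rr - pr[s])^2, (cc - pc[s])^2, "+") /
                           (2 * width^2))
          blk <- fibers[rr + 1L, cc + 1L, drop = FALSE]
          fibers[rr + 1L, cc + 1L] <- pmax(blk, g)  # max-splat: no self-overlap brightening
        }
      }
    }
    px <- if (channels == 1L) {
      array(backgroundLevel + cells + fibers, dim = c(H, W, 1L))
    } else if (channels == 2L) {
      array(c(backgroundLevel + cells, backgroundLevel + fibers),
            dim = c(H, W, 2L))
    } else {
      array(c(backgroundLevel + cells, backgroundLevel + fibers,
              backgroundLevel + 0.5 * (cells + fibers)), dim = c(H, W, 3L))
    }
    ImageRaster(clipRange(px, 0, 1))
  })
}

# Within-tile falloff: 0 at tile boundary, 1 at tile centre (raised cosine).
tileProfile <- function(t) 0.5 - 0.5 * cospi(2 * t)

# 1-d shading value from a continuous tile coordinate u and period tile.
stripeValue1d <- function(u, tile, amplitude) {
  t <- (u %% tile) / tile
  (1 - amplitude) + amplitude * tileProfile(t)
}

#' Render a stripe shading field
#'
#' Evaluates a [StripeModel-class] over an `H x W` raster, producing the
#' strictly positive multiplicative field whose minima lie along tile
#' boundaries (intensity falls off from the centre of each tile).
#'
#' * `uniform` — one within-tile raised-cosine profile across columns,
#'   repeated over the tile grid (vertical stripes);
#' * `non_uniform` — the same, but each tile's amplitude and overall gain
#'   jittered (seeded) by `perTileJitter`;
#' * `grid` — elementwise product of a row-period and a column-period field;
#' * `oblique` — the uniform field evaluated in coordinates rotated by
#'   `angleTheta` degrees (no image resampling, so no interpolation error).
#'
#' @param model a [StripeModel-class].
#' @param size `(H, W)` in pixels; at least one tile.
#' @param seed seed for `non_uniform` jitter (ignored otherwise).
#' @return a [ShadingField-class].
#' @examples
#' f <- makeStripeField(StripeModel("grid", 32, 32, 0.4), c(96, 96))
#' range(fieldValues(f))
#' @export
makeStripeField <- function(model, size, seed = 0L) {
  H <- as.integer(size[1]); W <- as.integer(size[2])
  if (H < model@tileH && W < model@tileW)
    invalidArgument("raster must span at least one tile")
  a <- model@amplitude
  rows <- seq_len(H) - 0.5  # pixel centres
  cols <- seq_len(W) - 0.5
  vals <- switch(model@kind,
    uniform = {
      v <- stripeValue1d(cols, model@tileW, a)
      matrix(v, H, W, byrow = TRUE)
    },
    oblique = {
      th <- model@angleTheta / 180
      u <- outer(rows * sinpi(th), cols * cospi(th), "+")
      stripeValue1d(u, model@tileW, a)
    },
    grid = {
      pr <- stripeValue1d(rows, model@tileH, a)
      pc <- stripeValue1d(cols, model@tileW, a)
      outer(pr, pc)
    },
    non_uniform = {
      base <- stripeValue1d(cols, model@tileW, a)
      out <- matrix(0, H, W)
      nTr <- ceiling(H / model@tileH)
      nTc <- ceiling(W / model@tileW)
      withSeed(seed, {
        for (ti in seq_len(nTr)) {
          for (tj in seq_len(nTc)) {
            at <- min(0.98, max(0, a * (1 + model@perTileJitter * rnorm(1))))
            gain <- 1 - 0.5 * model@perTileJitter * runif(1)
            rs <- ((ti - 1L) * model@tileH + 1L):min(H, ti * model@tileH)
            cs <- ((tj - 1L) * model@tileW + 1L):min(W, tj * model@tileW)
            tt <- ((cs - 0.5) %% model@tileW) / model@tileW
            prof <- gain * ((1 - at) + at * tileProfile(tt))
            out[rs, cs] <- matrix(prof, length(rs), length(cs), byrow = TRUE)
          }
        }
      })
      out
    },
    invalidArgument("unknown stripe kind"))
  new("ShadingField", values = vals, model = model)
}

#' Apply a multiplicative shading field to an image
#'
#' `out = clip(img * field)` channel-wise. Where no clipping occurs the
#' degradation is exactly invertible by dividing by the (known) field.
#'
#' @param img an [ImageRaster-class].
#' @param field a [ShadingField-class] of matching size.
#' @return the degraded [ImageRaster-class].
#' @export
applyStripeField <- function(img, field) {
  p <- img@pixels
  v <- field@values
  if (nrow(v) != dim(p)[1] || ncol(v) != dim(p)[2])
    invalidArgument("field size must match image size")
  out <- p * as.vector(v)  # recycles over channels (H*W blocks)
  ImageRaster(clipRange(out, img@valueRange[1], img@valueRange[2]),
              valueRange = img@valueRange, channelNames = img@channelNames)
}

# Euclidean distance from each pixel centre-index to the artifact region
# (0 inside). Used for outward feathering.
regionOutsideDistance <- function(spec, H, W) {
  r <- seq_len(H) - 1L
  c <- seq_len(W) - 1L
  if (spec@regionType == "rect") {
    q <- spec@region
    dr <- pmax(q[1] - r, r - (q[3] - 1), 0)
    dc <- pmax(q[2] - c, c - (q[4] - 1), 0)
    sqrt(outer(dr^2, dc^2, "+"))
  } else {
    d <- sqrt(outer((r - spec@region[1])^2, (c - spec@region[2])^2, "+"))
    pmax(d - spec@region[3], 0)
  }
}

regionInsideMask <- function(spec, H, W) {
  regionOutsideDistance(spec, H, W) == 0
}

checkRegionInside <- function(spec, H, W) {
  q <- spec@region
  ok <- if (spec@regionType == "rect") {
    q[1] >= 0 && q[2] >= 0 && q[3] <= H && q[4] <= W && q[3] > q[1] && q[4] > q[2]
  } else {
    q[3] > 0 && q[1] - q[3] >= -0.5 && q[2] - q[3] >= -0.5 &&
      q[1] + q[3] <= H - 0.5 && q[2] + q[3] <= W - 0.5
  }
  if (!ok) invalidArgument("artifact region lies outside the image")
}

#' Apply a local artifact to an image
#'
#' Three parametric degradations, applied per channel inside the spec's
#' region:
#' * `out_of_focus` — Gaussian blur (`blurSigma`) then multiplication by
#'   `attenuation`, feathered over an 8-px linear ramp outside the region
#'   boundary so no hard edge is introduced;
#' * `scan_fringe` — multiplication by
#'   `1 + fringeAmplitude * sin(2*pi*row/fringePeriod + phase(seed))`,
#'   emulating resonant-scanner ripple;
#' * `bubble` — radial attenuation inside a disk with a darker raised-cosine
#'   rim of width `rimWidth` reaching multiplier `1 - depth`, plus a mild
#'   interior haze, emulating local tissue moisture loss.
#'
#' @param img an [ImageRaster-class].
#' @param spec an [ArtifactSpec-class] whose region lies inside the image.
#' @return the degraded [ImageRaster-class].
#' @export
applyArtifact <- function(img, spec) {
  p <- img@pixels
  H <- dim(p)[1]; W <- dim(p)[2]; C <- dim(p)[3]
  checkRegionInside(spec, H, W)
  lo <- img@valueRange[1]; hi <- img@valueRange[2]
  out <- switch(spec@kind,
    out_of_focus = {
      dOut <- regionOutsideDistance(spec, H, W)
      w <- pmax(0, 1 - dOut / 8)   # 1 inside, linear ramp over 8 px outside
      res <- p
      for (ch in seq_len(C)) {
        bl <- if (spec@blurSigma > 0) gaussianBlurMatrix(p[, , ch], spec@blurSigma)
              else p[, , ch]
        # img + w * (target - img): exact identity where the artifact is a no-op
        res[, , ch] <- p[, , ch] + w * (spec@attenuation * bl - p[, , ch])
      }
      res
    },
    scan_fringe = {
      inside <- regionInsideMask(spec, H, W)
      phase <- withSeed(spec@seed, runif(1, 0, 2 * pi))
      rowMul <- 1 + spec@fringeAmplitude *
        sin(2 * pi * (seq_len(H) - 1L) / spec@fringePeriod + phase)
      mul <- matrix(1, H, W)
      mul[inside] <- matrix(rowMul, H, W)[inside]
      p * as.vector(mul)
    },
    bubble = {
      if (spec@regionType != "disk")
        invalidArgument("bubble artifacts require a disk region")
      R <- spec@region[3]
      if (spec@rimWidth >= R)
        invalidArgument("rimWidth must be smaller than the bubble radius")
      r <- seq_len(H) - 1L; c <- seq_len(W) - 1L
      rho <- sqrt(outer((r - spec@region[1])^2, (c - spec@region[2])^2, "+"))
      rim0 <- R - spec@rimWidth
      # raised-cosine rim dip, zero at both band edges (continuous field)
      g <- ifelse(rho >= rim0 & rho <= R,
                  0.5 * (1 + cospi(2 * (rho - (R - spec@rimWidth / 2)) /
                                     spec@rimWidth)), 0)
      haze <- ifelse(rho < rim0, 0.25 * (1 - (rho / rim0)^2), 0)
      mul <- 1 - spec@depth * g - spec@depth * haze
      p * as.vector(mul)
    },
    invalidArgument("unknown artifact kind"))
  ImageRaster(clipRange(out, lo, hi), valueRange = img@valueRange,
              channelNames = img@channelNames)
}

#' Write a synthetic fixture set to disk
#'
#' Emits the (clean, degraded, field, mask) quadruple as TIFF files, the
#' anomaly mask additionally as an 8-bit PNG in `{0, 255}`, and a YAML
#' manifest of every generating parameter.
#'
#' @param dir output directory (created if missing).
#' @param clean,degraded [ImageRaster-class] objects.
#' @param field a [ShadingField-class].
#' @param mask a [RegionMask-class].
#' @param params named list recorded verbatim in the manifest.
#' @return invisibly, the manifest path.
#' @export
writeFixtureSet <- function(dir, clean, degraded, field, mask, params = list()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeImage(clean, file.path(dir, "clean.tif"), bitDepth = 16)
  writeImage(degraded, file.path(dir, "degraded.tif"), bitDepth = 16)
  writeImage(ImageRaster(field@values), file.path(dir, "field.tif"),
             bitDepth = 32)
  png::writePNG(ifelse(mask@mask, 1, 0), file.path(dir, "mask.png"))
  manifest <- file.path(dir, "manifest.yaml")
  yaml::write_yaml(c(params, list(
    files = c("clean.tif", "degraded.tif", "field.tif", "mask.png"))),
    manifest)
  invisible(manifest)
}
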