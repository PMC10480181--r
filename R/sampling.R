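#' Anomaly mask from a rough tile-grid annotation
#'
#' Users annotate only the tile geometry (tile size, band half-width,
#' optional obliqueness); every pixel within `bandHalfwidth` of a tile
#' boundary line — both line families, rotated by `angleTheta` degrees — is
#' marked anomaly. Boundary lines sit at integer multiples of the tile side,
#' including the raster edges.
#'
#' @param size `(H, W)`.
#' @param tileH,tileW tile sides in pixels.
#' @param bandHalfwidth half-width of the anomaly band in pixels; must be
#'   below `min(tileH, tileW) / 2`.
#' @param angleTheta stripe angle in degrees.
#' @return a [RegionMask-class] with provenance `"tile_grid"`.
#' @examples
#' m <- maskFromTileGrid(c(256, 256), 128, 128, 4)
#' mean(maskMatrix(m))
#' @export
maskFromTileGrid <- function(size, tileH, tileW, bandHalfwidth,
                             angleTheta = 0) {
  H <- as.integer(size[1]); W <- as.integer(size[2])
  if (bandHalfwidth >= min(tileH, tileW) / 2)
    invalidArgument("bandHalfwidth must be below half the smallest tile side")
  th <- angleTheta / 180
  r <- seq_len(H) - 1L
  c <- seq_len(W) - 1L
  # rotation preserves distances, so distance-to-line is computed in the
  # rotated frame by modular arithmetic
  u <- outer(r * sinpi(th), c * cospi(th), "+")      # column-line coordinate
  v <- outer(r * cospi(th), -c * sinpi(th), "+")     # row-line coordinate
  mu <- u %% tileW
  mv <- v %% tileH
  du <- pmin(mu, tileW - mu)
  dv <- pmin(mv, tileH - mv)
  mask <- du <= bandHalfwidth | dv <= bandHalfwidth
  if (all(mask)) invalidArgument("band covers the entire image")
  RegionMask(mask, provenance = "tile_grid")
}

#' Anomaly mask from an artifact region
#'
#' Marks every pixel inside the spec's rectangle or disk.
#'
#' @param spec an [ArtifactSpec-class].
#' @param size `(H, W)`.
#' @return a [RegionMask-class] with provenance `"artifact_region"`.
#' @export
maskFromArtifact <- function(spec, size) {
  H <- as.integer(size[1]); W <- as.integer(size[2])
  checkRegionInside(spec, H, W)
  RegionMask(regionInsideMask(spec, H, W), provenance = "artifact_region")
}

# Origin lattice per axis: multiples of `stride` in [0, len - P], plus the
# clamped final origin so the border is reachable.
axisLattice <- function(len, P, stride) {
  sort(unique(c(seq.int(0L, len - P, by = stride), len - P)))
}

# Count of anomaly pixels in every P x P window with origin on the lattice,
# via a summed-area table. Returns a data.frame (row, col, count).
latticeAnomalyCounts <- function(mask, P, stride) {
  H <- nrow(mask); W <- ncol(mask)
  S <- rbind(0, cbind(0, apply(apply(mask, 2, cumsum), 1, cumsum)))
  # S is now (W+1) x (H+1) because of the transposing apply; fix orientation
  S <- t(S)
  rs <- axisLattice(H, P, stride)
  cs <- axisLattice(W, P, stride)
  grid <- expand.grid(row = rs, col = cs)
  r0 <- grid$row; c0 <- grid$col
  cnt <- S[cbind(r0 + P + 1L, c0 + P + 1L)] - S[cbind(r0 + 1L, c0 + P + 1L)] -
    S[cbind(r0 + P + 1L, c0 + 1L)] + S[cbind(r0 + 1L, c0 + 1L)]
  grid$count <- as.integer(round(cnt))
  grid
}

extractPatch <- function(px, r0, c0, P) {
  px[(r0 + 1L):(r0 + P), (c0 + 1L):(c0 + P), , drop = FALSE]
}

#' Sample anomaly patches on a mask
#'
#' Draws up to `n` patch origins, without replacement, from the
#' stride-quantized origin lattice, keeping only windows whose
#' anomaly-pixel fraction is at least `minOverlap`. Patches must be smaller
#' than the acquisition tile so each window sees at most one stripe.
#'
#' @param img an [ImageRaster-class].
#' @param mask a [RegionMask-class] of matching size.
#' @param patch patch side P.
#' @param n number of patches requested.
#' @param minOverlap minimum anomaly-pixel fraction per window (default 0.3,
#'   suited to stripe bands; use ~0.6 for compact artifacts).
#' @param seed sampling seed.
#' @param stride origin lattice stride; defaults to `P %/% 4`.
#' @return list with `origins` (n x 2, 0-based), `patches` (list of arrays),
#'   `fractions`, and `truncated` (TRUE when fewer than `n` admissible
#'   origins existed — also signalled as a warning).
#' @export
sampleAnomalyPatches <- function(img, mask, patch, n, minOverlap = 0.3,
                                 seed = 1L, stride = NULL) {
  P <- as.integer(patch)
  m <- mask@mask
  px <- img@pixels
  if (nrow(m) != dim(px)[1] || ncol(m) != dim(px)[2])
    invalidArgument("mask size must match image size")
  if (P > min(dim(m))) invalidArgument("patch must fit inside the image")
  if (is.null(stride)) stride <- max(1L, P %/% 4L)
  cand <- latticeAnomalyCounts(m, P, as.integer(stride))
  need <- minOverlap * P * P
  adm <- cand[cand$count >= need - 1e-9, , drop = FALSE]
  truncated <- nrow(adm) < n
  if (nrow(adm) == 0L) {
    warning("no admissible anomaly origins; returning an empty sample")
    return(list(origins = matrix(integer(0), 0, 2), patches = list(),
                fractions = numeric(0), truncated = TRUE))
  }
  idx <- if (truncated) {
    warning(sprintf("only %d admissible anomaly origins (requested %d)",
                    nrow(adm), n))
    seq_len(nrow(adm))
  } else withSeed(seed, sample.int(nrow(adm), n))
  sel <- adm[idx, , drop = FALSE]
  list(origins = cbind(row = as.integer(sel$row), col = as.integer(sel$col)),
       patches = lapply(seq_len(nrow(sel)), function(i)
         extractPatch(px, sel$row[i], sel$col[i], P)),
       fractions = sel$count / (P * P),
       truncated = truncated)
}

#' Pair each anomaly patch with its nearest normal patch
#'
#' For every anomaly origin, chooses the admissible normal origin — a
#' lattice window containing zero anomaly pixels — minimizing the
#' centre-to-centre Euclidean distance; ties are broken deterministically by
#' smaller row, then smaller column. Pairing anomaly and normal patches in
#' proximity keeps illumination and texture context shared between the two
#' domains.
#'
#' @param anomalyOrigins integer `n x 2` matrix of 0-based origins.
#' @param img an [ImageRaster-class].
#' @param mask a [RegionMask-class].
#' @param patch patch side P.
#' @param stride lattice stride; defaults to `P %/% 4`.
#' @return list of [PatchPair-class] objects.
#' @export
pairNearestNormal <- function(anomalyOrigins, img, mask, patch,
                              stride = NULL) {
  P <- as.integer(patch)
  if (is.null(stride)) stride <- max(1L, P %/% 4L)
  cand <- latticeAnomalyCounts(mask@mask, P, as.integer(stride))
  normals <- cand[cand$count == 0L, , drop = FALSE]
  if (nrow(normals) == 0L)
    stop(errorCondition(
      "unsatisfiable pairing: no lattice window is free of anomaly pixels",
      class = c("stripecor_unsatisfiable_pairing", "error")))
  # order so that which.min's first-match rule realizes the tie-break
  normals <- normals[order(normals$row, normals$col), , drop = FALSE]
  px <- img@pixels
  lapply(seq_len(nrow(anomalyOrigins)), function(i) {
    ar <- anomalyOrigins[i, 1]; ac <- anomalyOrigins[i, 2]
    d2 <- (normals$row - ar)^2 + (normals$col - ac)^2
    j <- which.min(d2)
    new("PatchPair",
        anomaly = extractPatch(px, ar, ac, P),
        normal = extractPatch(px, normals$row[j], normals$col[j], P),
        anomalyOrigin = as.integer(c(ar, ac)),
        normalOrigin = as.integer(c(normals$row[j], normals$col[j])),
        pairDistance = sqrt(d2[j]))
  })
}

#' Build the proximity-sampled training set
#'
#' Composes [sampleAnomalyPatches()] and [pairNearestNormal()] into the
#' [TrainingSet-class] consumed by [trainSelfCorrection()]. When a tile
#' geometry is supplied in `cfg`, the patch-size guard
#' `P < min(tileH, tileW)` is enforced.
#'
#' @param img an [ImageRaster-class].
#' @param mask a [RegionMask-class] with at least one anomaly and one normal
#'   pixel.
#' @param cfg list with `patch`, `n`, and optionally `minOverlap`, `stride`,
#'   `seed`, `tileH`, `tileW`.
#' @return a [TrainingSet-class].
#' @export
buildTrainingSet <- function(img, mask, cfg) {
  if (!any(mask@mask) || all(mask@mask))
    invalidArgument("mask must contain both anomaly and normal pixels")
  P <- as.integer(cfg$patch)
  if (!is.null(cfg$tileH) && P >= min(cfg$tileH, cfg$tileW))
    invalidArgument("patch must be smaller than the tile size")
  minOverlap <- if (is.null(cfg$minOverlap)) 0.3 else cfg$minOverlap
  seed <- if (is.null(cfg$seed)) 1L else cfg$seed
  stride <- if (is.null(cfg$stride)) max(1L, P %/% 4L) else as.integer(cfg$stride)
  if (cfg$n == 0L)
    return(new("TrainingSet", x = list(), y = list(),
               xOrigins = matrix(integer(0), 0, 2),
               yOrigins = matrix(integer(0), 0, 2),
               pairDistance = numeric(0), patch = P, truncated = FALSE))
  anom <- sampleAnomalyPatches(img, mask, P, cfg$n, minOverlap, seed, stride)
  if (nrow(anom$origins) == 0L)
    invalidArgument("no admissible anomaly patches under the given mask")
  pairs <- pairNearestNormal(anom$origins, img, mask, P, stride)
  ts <- new("TrainingSet",
            x = lapply(pairs, function(p) p@anomaly),
            y = lapply(pairs, function(p) p@normal),
            xOrigins = anom$origins,
            yOrigins = do.call(rbind, lapply(pairs, function(p)
              p@normalOrigin)),
            pairDistance = vapply(pairs, function(p) p@pairDistance,
                                  numeric(1)),
            patch = P, truncated = anom$truncated)
  message(sprintf(
    "training set: %d pairs, patch %d, pair distance %.1f-%.1f px (median %.1f)",
    nPairs(ts), P, min(ts@pairDistance), max(ts@pairDistance),
    stats::median(ts@pairDistance)))
  ts
}
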