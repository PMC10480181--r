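#' ImageRaster: an in-memory multi-channel image
#'
#' The central raster container: an `H x W x C` array of intensities with a
#' declared value range (default `[0, 1]`, the package's internal currency)
#' and optional channel names. Everything in the package — phantoms,
#' degraded mosaics, corrected outputs — is an `ImageRaster`.
#'
#' @slot pixels numeric `H x W x C` array; all values finite and inside
#'   `valueRange`.
#' @slot valueRange numeric length-2 `(lo, hi)`, `lo < hi`.
#' @slot channelNames character of length `C`.
#' @export
setClass("ImageRaster",
  representation(pixels = "array", valueRange = "numeric",
                 channelNames = "character"),
  prototype(valueRange = c(0, 1)))

setValidity("ImageRaster", function(object) {
  p <- object@pixels
  d <- dim(p)
  if (length(d) != 3L) return("pixels must be an H x W x C array")
  if (d[1] < 1L || d[2] < 1L) return("H and W must be >= 1")
  if (!d[3] %in% 1:3) return("channel count must be 1, 2 or 3")
  if (!all(is.finite(p))) return("pixels must be finite")
  vr <- object@valueRange
  if (length(vr) != 2L || !all(is.finite(vr)) || vr[1] >= vr[2])
    return("valueRange must be finite (lo, hi) with lo < hi")
  if (min(p) < vr[1] - 1e-12 || max(p) > vr[2] + 1e-12)
    return("pixels fall outside the declared value range")
  if (length(object@channelNames) != d[3])
    return("channelNames length must equal channel count")
  TRUE
})

#' Construct an ImageRaster
#'
#' @param pixels `H x W x C` array or `H x W` matrix (treated as one channel).
#' @param valueRange declared `(lo, hi)`; values are clipped on construction.
#' @param channelNames optional channel labels.
#' @return an [ImageRaster-class] object.
#' @examples
#' img <- ImageRaster(matrix(runif(64), 8, 8))
#' dim(pixels(img))
#' @export
ImageRaster <- function(pixels, valueRange = c(0, 1), channelNames = NULL) {
  p <- asPixelArray(pixels)
  p <- clipRange(p, valueRange[1], valueRange[2])
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(dim(p)[3]))
  new("ImageRaster", pixels = p, valueRange = as.numeric(valueRange),
      channelNames = as.character(channelNames))
}

#' Parametric description of stitched-mosaic stripe shading
#'
#' Describes the multiplicative tile-shading pattern of a stitched mosaic:
#' the tile geometry, the fractional shading depth, and the stripe flavour —
#' `uniform` (one within-tile profile repeated), `non_uniform` (per-tile
#' jittered profiles), `grid` (both axes), or `oblique` (tile boundaries
#' rotated by `angleTheta` degrees).
#'
#' @slot kind one of `"uniform"`, `"non_uniform"`, `"grid"`, `"oblique"`.
#' @slot tileH,tileW tile height/width in pixels (>= 8).
#' @slot amplitude fractional shading depth in `[0, 1)`.
#' @slot angleTheta stripe angle in degrees; must be 0 unless `kind` is
#'   `"oblique"`.
#' @slot perTileJitter relative std of per-tile variation (`non_uniform`).
#' @slot profile within-tile falloff shape; `"raised_cosine"`.
#' @export
setClass("StripeModel",
  representation(kind = "character", tileH = "integer", tileW = "integer",
                 amplitude = "numeric", angleTheta = "numeric",
                 perTileJitter = "numeric", profile = "character"))

setValidity("StripeModel", function(object) {
  if (!object@kind %in% c("uniform", "non_uniform", "grid", "oblique"))
    return("unknown stripe kind")
  if (object@tileH < 8L || object@tileW < 8L) return("tile sides must be >= 8")
  if (object@amplitude < 0 || object@amplitude >= 1)
    return("amplitude must lie in [0, 1)")
  if (object@kind != "oblique" && object@angleTheta != 0)
    return("angleTheta must be 0 unless kind is 'oblique'")
  if (object@perTileJitter < 0) return("perTileJitter must be >= 0")
  TRUE
})

#' @param kind,tileH,tileW,amplitude,angleTheta,perTileJitter,profile see slots.
#' @return a [StripeModel-class] object.
#' @rdname StripeModel-class
#' @export
StripeModel <- function(kind = "uniform", tileH = 128, tileW = 128,
                        amplitude = 0.5, angleTheta = 0,
                        perTileJitter = 0.2, profile = "raised_cosine") {
  new("StripeModel", kind = kind, tileH = as.integer(tileH),
      tileW = as.integer(tileW), amplitude = as.numeric(amplitude),
      angleTheta = as.numeric(angleTheta),
      perTileJitter = as.numeric(perTileJitter), profile = profile)
}

#' A realized multiplicative shading field
#'
#' The `H x W` field of strictly positive multipliers produced by rendering a
#' [StripeModel-class] at a given raster size. Shading attenuates, never
#' amplifies: `0 < values <= 1`.
#'
#' @slot values numeric matrix of multipliers.
#' @slot model the generating [StripeModel-class].
#' @export
setClass("ShadingField",
  representation(values = "matrix", model = "StripeModel"))

setValidity("ShadingField", function(object) {
  v <- object@values
  if (!all(is.finite(v))) return("field values must be finite")
  if (min(v) <= 0) return("field must be strictly positive")
  if (max(v) > 1 + 1e-12) return("field must not exceed 1 (shading attenuates)")
  TRUE
})

#' Parametric description of a local artifact
#'
#' One of three local degradations seen in stitched microscopy mosaics:
#' `out_of_focus` (blur plus attenuation inside a region, feathered at its
#' boundary), `scan_fringe` (periodic row-wise intensity ripple from a
#' resonant scanner), or `bubble` (disk-shaped distortion with a darker rim,
#' as caused by local tissue moisture loss).
#'
#' @slot kind one of `"out_of_focus"`, `"scan_fringe"`, `"bubble"`.
#' @slot regionType `"rect"` or `"disk"`.
#' @slot region for `"rect"`: `(row0, col0, row1, col1)` half-open, 0-based;
#'   for `"disk"`: `(centerRow, centerCol, radius)`.
#' @slot blurSigma Gaussian blur sigma in pixels (out_of_focus).
#' @slot attenuation multiplicative factor in `(0, 1]` (out_of_focus).
#' @slot fringePeriod,fringeAmplitude ripple period (pixels) and fractional
#'   amplitude (scan_fringe).
#' @slot rimWidth,depth rim width in pixels and fractional depth (bubble).
#' @slot seed integer seed for the artifact's stochastic phase.
#' @export
setClass("ArtifactSpec",
  representation(kind = "character", regionType = "character",
                 region = "numeric", blurSigma = "numeric",
                 attenuation = "numeric", fringePeriod = "numeric",
                 fringeAmplitude = "numeric", rimWidth = "numeric",
                 depth = "numeric", seed = "integer"),
  prototype(blurSigma = 0, attenuation = 1, fringePeriod = 8,
            fringeAmplitude = 0, rimWidth = 4, depth = 0, seed = 0L))

setValidity("ArtifactSpec", function(object) {
  if (!object@kind %in% c("out_of_focus", "scan_fringe", "bubble"))
    return("unknown artifact kind")
  if (!object@regionType %in% c("rect", "disk"))
    return("regionType must be 'rect' or 'disk'")
  n <- if (object@regionType == "rect") 4L else 3L
  if (length(object@region) != n)
    return("region must have 4 (rect) or 3 (disk) coordinates")
  if (object@blurSigma < 0) return("blurSigma must be >= 0")
  if (object@attenuation <= 0 || object@attenuation > 1)
    return("attenuation must lie in (0, 1]")
  if (object@fringePeriod < 2) return("fringePeriod must be >= 2 pixels")
  if (object@fringeAmplitude < 0 || object@fringeAmplitude >= 1)
    return("fringeAmplitude must lie in [0, 1)")
  if (object@rimWidth <= 0) return("rimWidth must be > 0")
  if (object@depth < 0 || object@depth >= 1)
    return("depth must lie in [0, 1)")
  TRUE
})

#' @param kind,regionType,region,blurSigma,attenuation,fringePeriod,fringeAmplitude,rimWidth,depth,seed
#'   see slots.
#' @return an [ArtifactSpec-class] object.
#' @rdname ArtifactSpec-class
#' @export
ArtifactSpec <- function(kind, regionType, region, blurSigma = 0,
                         attenuation = 1, fringePeriod = 8,
                         fringeAmplitude = 0, rimWidth = 4, depth = 0,
                         seed = 0) {
  new("ArtifactSpec", kind = kind, regionType = regionType,
      region = as.numeric(region), blurSigma = as.numeric(blurSigma),
      attenuation = as.numeric(attenuation),
      fringePeriod = as.numeric(fringePeriod),
      fringeAmplitude = as.numeric(fringeAmplitude),
      rimWidth = as.numeric(rimWidth), depth = as.numeric(depth),
      seed = as.integer(seed))
}

#' Boolean anomaly mask over a raster
#'
#' `TRUE` marks anomaly (on-stripe / in-artifact) pixels; `FALSE` marks
#' normal tissue. Produced from a tile-grid annotation
#' ([maskFromTileGrid()]), an artifact region, a user-supplied mask image,
#' or the simulator's ground truth.
#'
#' @slot mask logical `H x W` matrix.
#' @slot provenance one of `"tile_grid"`, `"user_mask"`, `"synthetic_truth"`,
#'   `"artifact_region"`.
#' @export
setClass("RegionMask",
  representation(mask = "matrix", provenance = "character"))

setValidity("RegionMask", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (any(is.na(object@mask))) return("mask must not contain NA")
  TRUE
})

#' @param mask logical matrix. @param provenance origin label.
#' @return a [RegionMask-class] object.
#' @rdname RegionMask-class
#' @export
RegionMask <- function(mask, provenance = "user_mask") {
  new("RegionMask", mask = mask, provenance = provenance)
}

#' An anomaly patch paired with its nearest normal patch
#'
#' The training unit of the method: a `P x P x C` patch sampled on the
#' anomaly region (domain X) together with the admissible normal patch
#' (domain Y, zero anomaly pixels) whose centre is nearest in Euclidean
#' distance.
#'
#' @slot anomaly,normal `P x P x C` arrays.
#' @slot anomalyOrigin,normalOrigin 0-based `(row, col)` of the patch
#'   top-left corners; windows are half-open `[r, r+P) x [c, c+P)`.
#' @slot pairDistance centre-to-centre Euclidean distance in pixels.
#' @export
setClass("PatchPair",
  representation(anomaly = "array", normal = "array",
                 anomalyOrigin = "integer", normalOrigin = "integer",
                 pairDistance = "numeric"))

#' A proximity-sampled training set
#'
#' All anomaly/normal patch pairs drawn from one image, plus bookkeeping.
#'
#' @slot x,y lists of `P x P x C` arrays (domains X and Y).
#' @slot xOrigins,yOrigins integer `n x 2` matrices of 0-based origins.
#' @slot pairDistance numeric vector of centre distances.
#' @slot patch patch side P.
#' @slot truncated TRUE when fewer than the requested number of anomaly
#'   patches were admissible.
#' @export
setClass("TrainingSet",
  representation(x = "list", y = "list", xOrigins = "matrix",
                 yOrigins = "matrix", pairDistance = "numeric",
                 patch = "integer", truncated = "logical"),
  prototype(truncated = FALSE))

#' Network architecture hyperparameters
#'
#' Defaults follow the published configuration: 256 x 256 patches, first
#' convolution to 64 feature channels, two stride-2 downsampling stages,
#' nine residual blocks, five-layer discriminator, instance normalization,
#' tanh output.
#'
#' @slot patchSize P; must be divisible by `2^nDownsample`.
#' @slot inChannels image channel count C.
#' @slot baseChannels feature channels after the first convolution.
#' @slot nDownsample number of stride-2 encoder stages.
#' @slot nResidualBlocks residual blocks in the bottleneck (>= 1).
#' @slot discLayers discriminator convolution count (>= 2).
#' @slot norm,finalActivation identifiers (`"instance"`, `"tanh"`).
#' @export
setClass("ArchitectureConfig",
  representation(patchSize = "integer", inChannels = "integer",
                 baseChannels = "integer", nDownsample = "integer",
                 nResidualBlocks = "integer", discLayers = "integer",
                 norm = "character", finalActivation = "character"),
  prototype(norm = "instance", finalActivation = "tanh"))

setValidity("ArchitectureConfig", function(object) {
  if (object@patchSize %% (2L^object@nDownsample) != 0L)
    return("patchSize must be divisible by 2^nDownsample")
  if (!object@inChannels %in% 1:3) return("inChannels must be 1, 2 or 3")
  if (object@nResidualBlocks < 1L) return("need at least one residual block")
  if (object@discLayers < 2L) return("need at least two discriminator layers")
  if (object@patchSize < 2L^object@discLayers)
    return("patchSize too small for discLayers stride-2 stages")
  if (object@baseChannels < 1L) return("baseChannels must be >= 1")
  TRUE
})

#' @param patchSize,inChannels,baseChannels,nDownsample,nResidualBlocks,discLayers,norm,finalActivation
#'   see slots.
#' @return an [ArchitectureConfig-class] object.
#' @rdname ArchitectureConfig-class
#' @export
ArchitectureConfig <- function(patchSize = 256, inChannels = 3,
                               baseChannels = 64, nDownsample = 2,
                               nResidualBlocks = 9, discLayers = 5,
                               norm = "instance", finalActivation = "tanh") {
  new("ArchitectureConfig", patchSize = as.integer(patchSize),
      inChannels = as.integer(inChannels),
      baseChannels = as.integer(baseChannels),
      nDownsample = as.integer(nDownsample),
      nResidualBlocks = as.integer(nResidualBlocks),
      discLayers = as.integer(discLayers), norm = norm,
      finalActivation = finalActivation)
}

#' The four learned sub-networks
#'
#' Holds the correction generator `gC` (anomaly -> normal), the synthesis
#' generator `gS` (normal -> anomaly; identical architecture), and the two
#' discriminators `dX`, `dY`, plus the architecture and training seed.
#'
#' @slot gC,gS,dX,dY network objects (lists of layers).
#' @slot arch the [ArchitectureConfig-class].
#' @slot seed integer training seed.
#' @export
setClass("CorrectionModel",
  representation(gC = "list", gS = "list", dX = "list", dY = "list",
                 arch = "ArchitectureConfig", seed = "integer"))

#' Training hyperparameters
#'
#' Defaults follow the published schedule: Adam with learning rate 2e-4 and
#' moment decay rates 0.5/0.999; 200 epochs with the rate held constant for
#' the first 100 and decayed linearly to zero over the last 100; consistency
#' weight lambda = 10; batch size 1.
#'
#' @slot lr0 initial learning rate.
#' @slot beta1,beta2 Adam moment decay rates.
#' @slot epochs,decayStartEpoch schedule (one traversal of the pair set per
#'   epoch).
#' @slot lambdaCons consistency-loss weight.
#' @slot batchSize pairs per step.
#' @slot seed master seed for init and data order.
#' @slot logEvery record a loss row every this many steps.
#' @slot maxSteps optional cap on total steps (`NA` = run all epochs).
#' @export
setClass("TrainingConfig",
  representation(lr0 = "numeric", beta1 = "numeric", beta2 = "numeric",
                 epochs = "integer", decayStartEpoch = "integer",
                 lambdaCons = "numeric", batchSize = "integer",
                 seed = "integer", logEvery = "integer",
                 maxSteps = "integer"))

setValidity("TrainingConfig", function(object) {
  if (object@lr0 <= 0) return("lr0 must be > 0")
  if (object@beta1 < 0 || object@beta1 >= 1 ||
      object@beta2 < 0 || object@beta2 >= 1)
    return("beta1 and beta2 must lie in [0, 1)")
  if (object@epochs < 0L) return("epochs must be >= 0")
  if (object@decayStartEpoch > object@epochs)
    return("decayStartEpoch must be <= epochs")
  if (object@lambdaCons < 0) return("lambdaCons must be >= 0")
  if (object@batchSize != 1L) return("only batchSize = 1 is supported")
  TRUE
})

#' @param lr0,beta1,beta2,epochs,decayStartEpoch,lambdaCons,batchSize,seed,logEvery,maxSteps
#'   see slots.
#' @return a [TrainingConfig-class] object.
#' @rdname TrainingConfig-class
#' @export
TrainingConfig <- function(lr0 = 2e-4, beta1 = 0.5, beta2 = 0.999,
                           epochs = 200, decayStartEpoch = 100,
                           lambdaCons = 10, batchSize = 1, seed = 1,
                           logEvery = 10, maxSteps = NA) {
  new("TrainingConfig", lr0 = as.numeric(lr0), beta1 = as.numeric(beta1),
      beta2 = as.numeric(beta2), epochs = as.integer(epochs),
      decayStartEpoch = as.integer(decayStartEpoch),
      lambdaCons = as.numeric(lambdaCons), batchSize = as.integer(batchSize),
      seed = as.integer(seed), logEvery = as.integer(logEvery),
      maxSteps = as.integer(maxSteps))
}

#' Sliding-window inference plan
#'
#' Window origins covering a raster with overlap, plus the per-window blend
#' weight map. Origins step by `step` per axis with the final origin clamped
#' so every window lies inside the raster; rasters smaller than the patch
#' are reflect-padded (recorded in `padH`, `padW`) and cropped after
#' merging.
#'
#' @slot patch window side P.
#' @slot step stride in pixels.
#' @slot origins integer `n x 2` matrix of 0-based `(row, col)` origins.
#' @slot weightMap numeric `P x P` non-negative blend weights.
#' @slot size the (possibly padded) raster size the plan covers.
#' @slot padH,padW reflect padding applied to reach at least P per axis.
#' @export
setClass("SlidingWindowPlan",
  representation(patch = "integer", step = "integer", origins = "matrix",
                 weightMap = "matrix", size = "integer", padH = "integer",
                 padW = "integer"))

setValidity("SlidingWindowPlan", function(object) {
  P <- object@patch
  o <- object@origins
  if (ncol(o) != 2L) return("origins must be an n x 2 matrix")
  H <- object@size[1]; W <- object@size[2]
  if (any(o < 0L) || any(o[, 1] > H - P) || any(o[, 2] > W - P))
    return("window origins must keep windows inside the raster")
  covR <- logical(H); covC <- logical(W)
  for (r in unique(o[, 1])) covR[(r + 1):(r + P)] <- TRUE
  for (c in unique(o[, 2])) covC[(c + 1):(c + P)] <- TRUE
  if (!all(covR) || !all(covC)) return("windows must cover every pixel")
  if (any(object@weightMap < 0)) return("weights must be non-negative")
  if (sum(object@weightMap) <= 0) return("weights must not be all zero")
  TRUE
})

#' Rectangular region of interest for metrics
#'
#' Half-open 0-based rectangle `[row0, row1) x [col0, col1)` with the
#' direction parallel to the stripes, along which intensities are averaged
#' when profiling.
#'
#' @slot rect numeric `(row0, col0, row1, col1)`.
#' @slot stripeAxis `"vertical"` (stripes vary across columns) or
#'   `"horizontal"`.
#' @export
setClass("ROI",
  representation(rect = "numeric", stripeAxis = "character"),
  prototype(stripeAxis = "vertical"))

setValidity("ROI", function(object) {
  r <- object@rect
  if (length(r) != 4L) return("rect must be (row0, col0, row1, col1)")
  if (r[3] <= r[1] || r[4] <= r[2]) return("ROI must be non-empty")
  if (!object@stripeAxis %in% c("horizontal", "vertical"))
    return("stripeAxis must be 'horizontal' or 'vertical'")
  TRUE
})

#' @param rect,stripeAxis see slots.
#' @return an [ROI-class] object.
#' @rdname ROI-class
#' @export
ROI <- function(rect, stripeAxis = "vertical") {
  new("ROI", rect = as.numeric(rect), stripeAxis = stripeAxis)
}

#' Quality metrics for a corrected image
#'
#' Per-ROI inverse coefficient of variation (mean over population standard
#' deviation; larger = flatter = better de-striping), intensity profiles,
#' and — when a clean reference exists — PSNR and SSIM.
#'
#' @slot icv,rA,rSd named numeric vectors, one element per ROI.
#' @slot icvPerChannel list of per-channel ICV vectors per ROI.
#' @slot profiles list of 1-d profiles per ROI.
#' @slot psnr dB, `Inf` when images are identical.
#' @slot psnrInfinite flag for the identical-image case.
#' @slot ssim unitless in `[-1, 1]`; `NA` without a reference.
#' @export
setClass("MetricsReport",
  representation(icv = "numeric", rA = "numeric", rSd = "numeric",
                 icvPerChannel = "list", profiles = "list",
                 psnr = "numeric", psnrInfinite = "logical",
                 ssim = "numeric"),
  prototype(psnr = NA_real_, psnrInfinite = FALSE, ssim = NA_real_))

#' Validated run configuration
#'
#' A schema-checked nested configuration for the pipeline stages; unknown
#' keys are rejected at read time.
#'
#' @slot stages named list of per-stage settings.
#' @slot seed global seed.
#' @slot outputDir artifact directory.
#' @slot verbosity 0 (quiet) to 2 (debug).
#' @export
setClass("RunConfig",
  representation(stages = "list", seed = "integer", outputDir = "character",
                 verbosity = "integer"))
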