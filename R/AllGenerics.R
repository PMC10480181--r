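#' Accessors for stripecor classes
#'
#' `pixels()`, `valueRange()` and `channelNames()` read the slots of an
#' [ImageRaster-class]; `fieldValues()` reads the multiplier matrix of a
#' [ShadingField-class]; `maskMatrix()` reads a [RegionMask-class];
#' `nPairs()` counts the pairs of a [TrainingSet-class].
#'
#' @param x the object.
#' @return the slot contents.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setMethod("pixels", "ImageRaster", function(x) x@pixels)

#' @rdname accessors
#' @export
setGeneric("valueRange", function(x) standardGeneric("valueRange"))
#' @rdname accessors
#' @export
setMethod("valueRange", "ImageRaster", function(x) x@valueRange)

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "ImageRaster", function(x) x@channelNames)

#' @rdname accessors
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))
#' @rdname accessors
#' @export
setMethod("fieldValues", "ShadingField", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("maskMatrix", function(x) standardGeneric("maskMatrix"))
#' @rdname accessors
#' @export
setMethod("maskMatrix", "RegionMask", function(x) x@mask)

#' @rdname accessors
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))
#' @rdname accessors
#' @export
setMethod("nPairs", "TrainingSet", function(x) length(x@x))

setMethod("dim", "ImageRaster", function(x) dim(x@pixels))

setMethod("show", "ImageRaster", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("ImageRaster %d x %d x %d, range [%g, %g], channels: %s\n",
              d[1], d[2], d[3], object@valueRange[1], object@valueRange[2],
              paste(object@channelNames, collapse = ", ")))
  cat(sprintf("  intensity: min %.4g, mean %.4g, max %.4g\n",
              min(object@pixels), mean(object@pixels), max(object@pixels)))
})

setMethod("show", "StripeModel", function(object) {
  cat(sprintf("StripeModel kind=%s tile=%dx%d amplitude=%.3g theta=%g%s\n",
              object@kind, object@tileH, object@tileW, object@amplitude,
              object@angleTheta,
              if (object@kind == "non_uniform")
                sprintf(" jitter=%.3g", object@perTileJitter) else ""))
})

setMethod("show", "ShadingField", function(object) {
  cat(sprintf("ShadingField %d x %d, multipliers in [%.4g, %.4g]\n",
              nrow(object@values), ncol(object@values),
              min(object@values), max(object@values)))
})

setMethod("show", "RegionMask", function(object) {
  cat(sprintf("RegionMask %d x %d (%s): %.1f%% anomaly\n",
              nrow(object@mask), ncol(object@mask), object@provenance,
              100 * mean(object@mask)))
})

setMethod("show", "TrainingSet", function(object) {
  cat(sprintf("TrainingSet: %d pairs, patch %d%s\n", length(object@x),
              object@patch, if (object@truncated) " (truncated)" else ""))
  if (length(object@pairDistance))
    cat(sprintf("  pair distance: min %.1f, median %.1f, max %.1f px\n",
                min(object@pairDistance), stats::median(object@pairDistance),
                max(object@pairDistance)))
})

setMethod("show", "ArchitectureConfig", function(object) {
  cat(sprintf(paste0("ArchitectureConfig: P=%d C=%d base=%d down=%d ",
                     "res=%d discLayers=%d norm=%s act=%s\n"),
              object@patchSize, object@inChannels, object@baseChannels,
              object@nDownsample, object@nResidualBlocks, object@discLayers,
              object@norm, object@finalActivation))
})

setMethod("show", "CorrectionModel", function(object) {
  cat("CorrectionModel (gC, gS, dX, dY)\n")
  show(object@arch)
  cat(sprintf("  trained with seed %d\n", object@seed))
})

setMethod("show", "SlidingWindowPlan", function(object) {
  cat(sprintf("SlidingWindowPlan: %d windows of %d px, step %d over %d x %d\n",
              nrow(object@origins), object@patch, object@step,
              object@size[1], object@size[2]))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport\n")
  if (length(object@icv))
    for (nm in names(object@icv))
      cat(sprintf("  ICV[%s] = %.4f (Ra %.4f / Rsd %.4f)\n", nm,
                  object@icv[[nm]], object@rA[[nm]], object@rSd[[nm]]))
  if (!is.na(object@psnr))
    cat(sprintf("  PSNR = %s dB%s\n",
                if (object@psnrInfinite) "Inf" else sprintf("%.3f", object@psnr),
                if (object@psnrInfinite) " (identical images)" else ""))
  if (!is.na(object@ssim)) cat(sprintf("  SSIM = %.5f\n", object@ssim))
})
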