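roiSlice <- function(px, roi) {
  r <- roi@rect
  px[(r[1] + 1L):r[3], (r[2] + 1L):r[4], , drop = FALSE]
}

luminance <- function(px) {
  if (dim(px)[3] == 1L) px[, , 1]
  else apply(px, c(1, 2), mean)
}

popSd <- function(v) sqrt(mean((v - mean(v))^2))

#' Inverse coefficient of variation of an ROI
#'
#' `ICV = Ra / Rsd`: the mean intensity of the ROI divided by the
#' population standard deviation of its intensities, computed on the
#' mean-across-channels luminance. A larger ICV means a flatter intensity
#' profile and therefore a better stripe correction. ICV is sensitive to
#' genuine image content — avoid black background when placing the ROI.
#'
#' @param img an [ImageRaster-class] (or numeric array/matrix).
#' @param roi an [ROI-class] inside the raster.
#' @return positive scalar; errors on a constant ROI (`Rsd = 0`).
#' @examples
#' icvValues(c(1, 2, 3, 4))  # 2.2360
#' @export
icv <- function(img, roi) {
  px <- if (is(img, "ImageRaster")) img@pixels else asPixelArray(img)
  icvValues(luminance(roiSlice(px, roi)))
}

#' @rdname icv
#' @param values numeric vector/matrix of ROI intensities.
#' @export
icvValues <- function(values) {
  v <- as.numeric(values)
  if (length(v) == 0L) invalidArgument("empty ROI")
  s <- popSd(v)
  if (s == 0)
    stop(errorCondition("undefined metric: ROI is constant (Rsd = 0)",
                        class = c("stripecor_undefined_metric", "error")))
  mean(v) / s
}

#' Intensity profile across stripes
#'
#' Averages ROI intensities along the stripe-parallel direction, yielding a
#' 1-d profile across the stripes: flat for a well-corrected image, rippled
#' for a striped one. For `stripeAxis = "vertical"` the profile has one
#' value per ROI column; for `"horizontal"`, one per row.
#'
#' @inheritParams icv
#' @return numeric vector.
#' @export
intensityProfile <- function(img, roi) {
  px <- if (is(img, "ImageRaster")) img@pixels else asPixelArray(img)
  lum <- luminance(roiSlice(px, roi))
  if (roi@stripeAxis == "vertical") colMeans(lum) else rowMeans(lum)
}

#' Peak signal-to-noise ratio
#'
#' `10 * log10(dataRange^2 / MSE)` in dB; identical inputs give `Inf`
#' (flagged in [evaluateCorrection()] reports).
#'
#' @param a,b [ImageRaster-class] objects or arrays of matching shape.
#' @param dataRange the dynamic range of the data (default 1).
#' @return scalar dB.
#' @export
psnr <- function(a, b, dataRange = 1) {
  pa <- if (is(a, "ImageRaster")) a@pixels else asPixelArray(a)
  pb <- if (is(b, "ImageRaster")) b@pixels else asPixelArray(b)
  if (!identical(dim(pa), dim(pb))) invalidArgument("shape mismatch in psnr")
  if (dataRange <= 0) invalidArgument("dataRange must be > 0")
  mse <- mean((pa - pb)^2)
  if (mse == 0) return(Inf)
  10 * log10(dataRange^2 / mse)
}

gaussianKernel1d <- function(size = 11L, sigma = 1.5) {
  r <- (size - 1L) / 2
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# 'valid' separable windowed filtering via band matrices.
validFilter <- function(m, k) {
  n <- length(k)
  H <- nrow(m); W <- ncol(m)
  Ho <- H - n + 1L; Wo <- W - n + 1L
  Kh <- matrix(0, Ho, H)
  for (i in seq_len(Ho)) Kh[i, i:(i + n - 1L)] <- k
  Kw <- matrix(0, Wo, W)
  for (i in seq_len(Wo)) Kw[i, i:(i + n - 1L)] <- k
  Kh %*% m %*% t(Kw)
}

#' Structural similarity index
#'
#' Mean local SSIM over an 11 x 11 Gaussian window (sigma 1.5) with the
#' standard stabilizers `K1 = 0.01`, `K2 = 0.03`; weighted local moments,
#' no sample-covariance correction. Multi-channel inputs are scored per
#' channel and averaged.
#'
#' @inheritParams psnr
#' @return scalar in `[-1, 1]`; 1 for identical images.
#' @export
ssim <- function(a, b, dataRange = 1) {
  pa <- if (is(a, "ImageRaster")) a@pixels else asPixelArray(a)
  pb <- if (is(b, "ImageRaster")) b@pixels else asPixelArray(b)
  if (!identical(dim(pa), dim(pb))) invalidArgument("shape mismatch in ssim")
  win <- 11L
  if (min(dim(pa)[1:2]) < win)
    invalidArgument("image smaller than the 11 x 11 SSIM window")
  k <- gaussianKernel1d(win, 1.5)
  C1 <- (0.01 * dataRange)^2
  C2 <- (0.03 * dataRange)^2
  perChannel <- vapply(seq_len(dim(pa)[3]), function(ch) {
    x <- pa[, , ch]; y <- pb[, , ch]
    mx <- validFilter(x, k); my <- validFilter(y, k)
    sxx <- validFilter(x * x, k) - mx^2
    syy <- validFilter(y * y, k) - my^2
    sxy <- validFilter(x * y, k) - mx * my
    s <- ((2 * mx * my + C1) * (2 * sxy + C2)) /
      ((mx^2 + my^2 + C1) * (sxx + syy + C2))
    mean(s)
  }, numeric(1))
  mean(perChannel)
}

#' Aggregate quality metrics into a report
#'
#' Computes per-ROI ICV (luminance and per channel) and intensity profiles;
#' when a clean reference raster is available, adds PSNR and SSIM. Without
#' ground truth — the usual microscopy situation — only the no-reference
#' metrics are reported.
#'
#' @param corrected an [ImageRaster-class].
#' @param reference optional clean [ImageRaster-class].
#' @param rois named list of [ROI-class] objects.
#' @param dataRange dynamic range for PSNR/SSIM.
#' @return a [MetricsReport-class].
#' @export
evaluateCorrection <- function(corrected, reference = NULL, rois = list(),
                               dataRange = 1) {
  if (length(rois) && is.null(names(rois)))
    names(rois) <- paste0("roi", seq_along(rois))
  px <- corrected@pixels
  icvs <- rAs <- rSds <- numeric(0)
  perCh <- profs <- list()
  for (nm in names(rois)) {
    v <- as.numeric(luminance(roiSlice(px, rois[[nm]])))
    icvs[nm] <- icvValues(v)
    rAs[nm] <- mean(v)
    rSds[nm] <- popSd(v)
    sl <- roiSlice(px, rois[[nm]])
    perCh[[nm]] <- vapply(seq_len(dim(px)[3]), function(ch)
      icvValues(sl[, , ch]), numeric(1))
    profs[[nm]] <- intensityProfile(corrected, rois[[nm]])
  }
  p <- NA_real_; s <- NA_real_; pinf <- FALSE
  if (!is.null(reference)) {
    p <- psnr(corrected, reference, dataRange)
    pinf <- is.infinite(p)
    s <- ssim(corrected, reference, dataRange)
  }
  new("MetricsReport", icv = icvs, rA = rAs, rSd = rSds,
      icvPerChannel = perCh, profiles = profs, psnr = p,
      psnrInfinite = pinf, ssim = s)
}

#' Serialize a metrics report
#'
#' Writes the report as JSON (non-finite PSNR encoded as a flag).
#'
#' @param report a [MetricsReport-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeMetricsReport <- function(report, path) {
  out <- list(
    icv = as.list(report@icv), rA = as.list(report@rA),
    rSd = as.list(report@rSd), icvPerChannel = report@icvPerChannel,
    profiles = report@profiles,
    psnr = if (report@psnrInfinite) NULL else report@psnr,
    psnrInfinite = report@psnrInfinite, ssim = report@ssim)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
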