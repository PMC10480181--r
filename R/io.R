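#' Read a raster image
#'
#' Reads TIFF (8/16-bit integer or 32-bit float) or PNG (8/16-bit) into an
#' [ImageRaster-class] with intensities rescaled to `[0, 1]` by the file's
#' bit depth; channel order is preserved. Alpha channels are rejected.
#'
#' @param path file path.
#' @return an [ImageRaster-class].
#' @export
readImage <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    p <- png::readPNG(path)
    if (length(dim(p)) == 3L && dim(p)[3] %in% c(2L, 4L))
      stop(sprintf("format error: %s carries an alpha channel", path))
    p
  } else stop(sprintf("format error: unsupported extension '%s' (%s)",
                      ext, path))
  px <- asPixelArray(px)
  if (!dim(px)[3] %in% 1:3)
    stop(sprintf("format error: %s has %d channels (1-3 supported)",
                 path, dim(px)[3]))
  # float TIFFs may stray outside [0,1]; integer reads are already scaled
  ImageRaster(clipRange(px, 0, 1))
}

#' Write a raster image
#'
#' Clips to the declared value range, rescales to `[0, 1]`, quantizes with
#' round-half-even to the requested bit depth, and writes TIFF (8, 16, or
#' 32-bit float) or PNG (8-bit).
#'
#' @param raster an [ImageRaster-class].
#' @param path output path (`.tif`/`.tiff` or `.png`).
#' @param bitDepth 8, 16, or 32 (float; TIFF only).
#' @return invisibly, `path`.
#' @export
writeImage <- function(raster, path, bitDepth = 16) {
  vr <- raster@valueRange
  x <- (clipRange(raster@pixels, vr[1], vr[2]) - vr[1]) / (vr[2] - vr[1])
  ext <- tolower(tools::file_ext(path))
  x <- quantizeUnit(x, bitDepth)
  if (ext %in% c("tif", "tiff")) {
    if (!bitDepth %in% c(8, 16, 32))
      invalidArgument("TIFF bitDepth must be 8, 16 or 32")
    tiff::writeTIFF(dropSingleChannel(x), path, bits.per.sample = bitDepth)
  } else if (ext == "png") {
    if (bitDepth != 8) invalidArgument("PNG output is written at 8 bits")
    png::writePNG(dropSingleChannel(x), path)
  } else invalidArgument(paste0("unsupported output extension: ", ext))
  invisible(path)
}

# round-half-even quantization to b bits; 32 means float passthrough
quantizeUnit <- function(x, b) {
  if (b == 32) return(x)
  m <- 2^b - 1
  round(x * m) / m
}

dropSingleChannel <- function(x) {
  if (dim(x)[3] == 1L) matrix(x[, , 1], dim(x)[1], dim(x)[2]) else x
}
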