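#' Blend weight map for sliding-window merging
#'
#' `uniform` weights are all ones (plain averaging over covering windows).
#' `feathered` weights ramp linearly from the patch edge to a plateau of 1
#' over `P %/% 4` pixels per axis (separable product), so window seams are
#' down-weighted; weights are strictly positive everywhere.
#'
#' @param patch patch side P (>= 2).
#' @param mode `"feathered"` (default) or `"uniform"`.
#' @return a `P x P` numeric weight matrix.
#' @export
blendWeights <- function(patch, mode = c("feathered", "uniform")) {
  mode <- match.arg(mode)
  P <- as.integer(patch)
  if (P < 2L) invalidArgument("patch must be >= 2")
  if (mode == "uniform") return(matrix(1, P, P))
  L <- max(1L, P %/% 4L)
  i <- seq_len(P)
  w1 <- pmin(1, pmin(i, P + 1L - i) / L)
  outer(w1, w1)
}

#' Plan sliding windows over a raster
#'
#' Window origins step by `step` along each axis, with the final origin
#' clamped to `H - P` (resp. `W - P`) so the last window stays inside the
#' raster; duplicates are removed. Rasters smaller than the patch are
#' handled by reflect-padding up to `P` (recorded in the plan and cropped
#' after merging). The published step conventions are half the patch size
#' (default) or a fixed 100 px.
#'
#' @param size `(H, W)` of the raster.
#' @param patch window side P.
#' @param step stride in pixels (>= 1), or `"half"` / `"100"`.
#' @param blend blend mode passed to [blendWeights()].
#' @return a [SlidingWindowPlan-class].
#' @examples
#' plan <- planWindows(c(512, 512), 256, 128)
#' nrow(plan@origins)  # 9
#' @export
planWindows <- function(size, patch, step = "half",
                        blend = c("feathered", "uniform")) {
  P <- as.integer(patch)
  step <- resolveStep(P, step)
  if (step < 1L) invalidArgument("step must be >= 1")
  if (step > P)
    invalidArgument("step must not exceed the patch size (windows must overlap or abut)")
  H <- as.integer(size[1]); W <- as.integer(size[2])
  padH <- max(0L, P - H); padW <- max(0L, P - W)
  H2 <- H + padH; W2 <- W + padW
  rs <- axisLattice(H2, P, step)
  cs <- axisLattice(W2, P, step)
  origins <- as.matrix(expand.grid(row = rs, col = cs))
  storage.mode(origins) <- "integer"
  new("SlidingWindowPlan", patch = P, step = step, origins = origins,
      weightMap = blendWeights(P, match.arg(blend)),
      size = c(H2, W2), padH = padH, padW = padW)
}

#' @rdname planWindows
#' @param patch,step see above.
#' @export
resolveStep <- function(patch, step) {
  if (identical(step, "half")) return(as.integer(patch) %/% 2L)
  if (identical(step, "100")) return(100L)
  as.integer(step)
}

reflectPadArray <- function(px, padH, padW) {
  if (padH == 0L && padW == 0L) return(px)
  d <- dim(px)
  tailReflect <- function(n, p) {
    # indices appended below/right of the raster, mirrored without edge reuse
    if (p == 0L) return(seq_len(n))
    c(seq_len(n), rev(seq_len(n))[seq_len(p) + 1L])
  }
  px[tailReflect(d[1], padH), tailReflect(d[2], padW), , drop = FALSE]
}

#' Local-to-global correction of a whole stitched image
#'
#' Maps every planned window through the trained correction generator in
#' `[-1, 1]` space and merges the results as a per-pixel weighted mean:
#' `out = sum(weight * patch) / sum(weight)`. With feathered weights the
#' merge suppresses visible window seams; by construction the merge is a
#' partition of unity, so a pass-through generator reproduces the input.
#'
#' @param img an [ImageRaster-class].
#' @param model a [CorrectionModel-class], a bare generator network, or a
#'   function mapping a `P x P x C` array in `[-1, 1]` to the same shape
#'   (useful for ablations such as the identity generator).
#' @param plan a [SlidingWindowPlan-class] for `dim(img)`.
#' @return the corrected [ImageRaster-class].
#' @export
correctWholeImage <- function(img, model, plan) {
  px <- img@pixels
  d <- dim(px)
  C <- d[3]
  gen <- if (is(model, "CorrectionModel")) {
    if (model@arch@inChannels != C)
      invalidArgument("model channel count does not match the image")
    function(p) netApply(model@gC, p)
  } else if (is.function(model)) {
    model
  } else if (is.list(model) && !is.null(model$layers)) {
    function(p) netApply(model, p)
  } else invalidArgument("model must be a CorrectionModel, network or function")

  lo <- img@valueRange[1]; hi <- img@valueRange[2]
  x <- toSigned((px - lo) / (hi - lo))
  x <- reflectPadArray(x, plan@padH, plan@padW)
  H2 <- plan@size[1]; W2 <- plan@size[2]
  P <- plan@patch
  num <- array(0, dim = c(H2, W2, C))
  den <- matrix(0, H2, W2)
  w <- plan@weightMap
  for (k in seq_len(nrow(plan@origins))) {
    r <- plan@origins[k, 1]; c <- plan@origins[k, 2]
    win <- x[(r + 1L):(r + P), (c + 1L):(c + P), , drop = FALSE]
    y <- gen(win)
    rs <- (r + 1L):(r + P); cs <- (c + 1L):(c + P)
    num[rs, cs, ] <- num[rs, cs, , drop = FALSE] + y * as.vector(w)
    den[rs, cs] <- den[rs, cs] + w
  }
  out <- num / as.vector(den)
  out <- out[seq_len(d[1]), seq_len(d[2]), , drop = FALSE]
  out <- lo + (hi - lo) * toUnit(out)
  ImageRaster(clipRange(out, lo, hi), valueRange = img@valueRange,
              channelNames = img@channelNames)
}
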