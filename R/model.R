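#' Build the correction (or synthesis) generator
#'
#' Encoder-decoder with a residual bottleneck: a stride-1 7x7 convolution
#' lifts the input to `baseChannels` features; each of `nDownsample`
#' stride-2 convolutions halves the spatial size and doubles the channels;
#' `nResidualBlocks` residual blocks with shortcut connections form the
#' bottleneck; mirrored stride-2 transpose convolutions restore the spatial
#' size; a final stride-1 7x7 convolution plus tanh emits `inChannels`
#' channels in `[-1, 1]`. Reflection padding is used throughout so patch
#' borders carry no zero-padding halo. The synthesis generator uses the
#' identical architecture.
#'
#' @param arch an [ArchitectureConfig-class].
#' @param seed weight-init seed (zero-mean Gaussian, sd 0.02).
#' @return a network object (list of layers) for [netApply()] /
#'   [trainSelfCorrection()].
#' @examples
#' g <- buildCorrectionNetwork(ArchitectureConfig(patchSize = 32,
#'   inChannels = 1, baseChannels = 8, nResidualBlocks = 2), seed = 1)
#' countResidualBlocks(g)
#' @export
buildCorrectionNetwork <- function(arch, seed = 1L) {
  if (arch@patchSize %% (2L^arch@nDownsample) != 0L)
    invalidArgument("patchSize must be divisible by 2^nDownsample")
  withSeed(seed, {
    layers <- list(nnPadReflect(3L),
                   nnConv(arch@inChannels, arch@baseChannels, 7L),
                   nnInstanceNorm(), nnReLU())
    ch <- arch@baseChannels
    for (i in seq_len(arch@nDownsample)) {
      layers <- c(layers, list(nnConv(ch, 2L * ch, 3L, stride = 2L, pad = 1L),
                               nnInstanceNorm(), nnReLU()))
      ch <- 2L * ch
    }
    for (i in seq_len(arch@nResidualBlocks))
      layers <- c(layers, list(nnResBlock(ch)))
    for (i in seq_len(arch@nDownsample)) {
      layers <- c(layers, list(nnConvT(ch, ch %/% 2L), nnInstanceNorm(),
                               nnReLU()))
      ch <- ch %/% 2L
    }
    layers <- c(layers, list(nnPadReflect(3L),
                             nnConv(ch, arch@inChannels, 7L), nnTanh()))
    list(kind = "generator", layers = layers)
  })
}

#' Build a patch discriminator
#'
#' `discLayers` convolutions (kernel 4): the first `discLayers - 1` extract
#' features at stride 2 with leaky-ReLU (slope 0.2) — instance-normalized
#' except the first — and the final stride-1 convolution is the classifier,
#' emitting a single-channel score map with no output nonlinearity
#' (least-squares adversarial convention).
#'
#' @inheritParams buildCorrectionNetwork
#' @return a network object.
#' @export
buildDiscriminator <- function(arch, seed = 1L) {
  withSeed(seed, {
    ch <- arch@baseChannels
    layers <- list(nnConv(arch@inChannels, ch, 4L, stride = 2L, pad = 1L),
                   nnLeakyReLU(0.2))
    for (i in seq_len(arch@discLayers - 2L)) {
      nxt <- 2L * ch
      layers <- c(layers, list(nnConv(ch, nxt, 4L, stride = 2L, pad = 1L),
                               nnInstanceNorm(), nnLeakyReLU(0.2)))
      ch <- nxt
    }
    layers <- c(layers, list(nnConv(ch, 1L, 4L, stride = 1L, pad = 1L)))
    list(kind = "discriminator", layers = layers)
  })
}

#' Run a network on one patch
#'
#' Forward pass without gradient bookkeeping. Generators expect and emit
#' `P x P x C` tensors in `[-1, 1]`; discriminators emit a single-channel
#' score map.
#'
#' @param net a network object.
#' @param x input array.
#' @return the output array.
#' @export
netApply <- function(net, x) netForward(net, x, keepCache = FALSE)$out

#' Introspect a network
#'
#' `countResidualBlocks()` and `countConvLayers()` count structural
#' elements; `layerOutChannels()` reports the output channel count of the
#' i-th convolution (including transpose convolutions, in network order).
#'
#' @param net a network object.
#' @param i convolution index.
#' @return an integer.
#' @export
countResidualBlocks <- function(net)
  sum(vapply(net$layers, function(l) identical(l$type, "res"), logical(1)))

#' @rdname countResidualBlocks
#' @export
countConvLayers <- function(net) {
  n <- 0L
  walk <- function(layers) for (l in layers) {
    if (l$type %in% c("conv", "convT")) n <<- n + 1L
    else if (l$type == "res") walk(l$layers)
  }
  walk(net$layers)
  n
}

#' @rdname countResidualBlocks
#' @export
layerOutChannels <- function(net, i) {
  convs <- Filter(function(l) l$type %in% c("conv", "convT"), net$layers)
  convs[[i]]$cout
}

#' Least-squares adversarial loss for a generator
#'
#' Mean over all discriminator score-map elements of `(1 - score)^2`: zero
#' when the discriminator is fully fooled.
#'
#' @param scores numeric array of discriminator scores on translated
#'   patches.
#' @return non-negative scalar.
#' @examples
#' advGeneratorLoss(0.5)  # 0.25
#' @export
advGeneratorLoss <- function(scores) {
  if (length(scores) == 0L) invalidArgument("empty score map")
  if (!all(is.finite(scores))) invalidArgument("scores must be finite")
  mean((1 - scores)^2)
}

#' Least-squares adversarial loss for a discriminator
#'
#' `mean((1 - realScores)^2) + mean(fakeScores^2)`: zero for a perfect
#' discriminator, 2 for a fully inverted one.
#'
#' @param realScores,fakeScores score maps on reference and translated
#'   patches.
#' @return non-negative scalar.
#' @export
discriminatorLoss <- function(realScores, fakeScores) {
  if (length(realScores) == 0L || length(fakeScores) == 0L)
    invalidArgument("empty score map")
  if (!all(is.finite(realScores)) || !all(is.finite(fakeScores)))
    invalidArgument("scores must be finite")
  mean((1 - realScores)^2) + mean(fakeScores^2)
}

#' Content-consistency loss
#'
#' L1 penalty on the two reciprocal round trips: anomaly patches destriped
#' then re-shaded (`gS(gC(x))` vs `x`), and normal patches shaded then
#' destriped (`gC(gS(y))` vs `y`). Keeps both generators content-preserving.
#'
#' @param x,xRec anomaly patch and its round-trip reconstruction.
#' @param y,yRec normal patch and its round-trip reconstruction.
#' @return non-negative scalar.
#' @export
consistencyLoss <- function(x, xRec, y, yRec) {
  if (!identical(dim(x) %||% length(x), dim(xRec) %||% length(xRec)) ||
      !identical(dim(y) %||% length(y), dim(yRec) %||% length(yRec)))
    invalidArgument("shape mismatch in consistency loss")
  mean(abs(x - xRec)) + mean(abs(y - yRec))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Total generator objective
#'
#' The generator share of the overall loss under standard alternation:
#' `lAdvGC + lAdvGS + lambdaCons * lCons` (each discriminator minimizes its
#' own term separately). The consistency weight defaults to 10.
#'
#' @param lAdvGC,lAdvGS,lCons the component losses (>= 0).
#' @param lambdaCons consistency weight (>= 0).
#' @return scalar.
#' @export
totalGeneratorObjective <- function(lAdvGC, lAdvGS, lCons, lambdaCons = 10) {
  if (lambdaCons < 0) invalidArgument("lambdaCons must be >= 0")
  lAdvGC + lAdvGS + lambdaCons * lCons
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single archive holding the four sub-networks, the
#' architecture, the training seed, and a schema version.
#'
#' @param model a [CorrectionModel-class].
#' @param path file path.
#' @return `readCorrectionModel()` returns the [CorrectionModel-class].
#' @export
saveCorrectionModel <- function(model, path) {
  saveRDS(list(schemaVersion = 1L, arch = model@arch, seed = model@seed,
               gC = model@gC, gS = model@gS, dX = model@dX, dY = model@dY),
          path)
  invisible(path)
}

#' @rdname saveCorrectionModel
#' @export
readCorrectionModel <- function(path) {
  ck <- readRDS(path)
  if (is.null(ck$schemaVersion) || ck$schemaVersion != 1L)
    stop("unsupported checkpoint schema")
  new("CorrectionModel", gC = ck$gC, gS = ck$gS, dX = ck$dX, dY = ck$dY,
      arch = ck$arch, seed = ck$seed)
}
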