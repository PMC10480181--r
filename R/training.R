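#' Learning-rate schedule
#'
#' Constant at `lr0` for the first `decayStartEpoch` epochs, then linear
#' decay reaching exactly zero at `epochs`.
#'
#' @param epoch integer in `[0, epochs]`.
#' @param cfg a [TrainingConfig-class].
#' @return the learning rate.
#' @examples
#' lrSchedule(150, TrainingConfig())  # 1e-4
#' @export
lrSchedule <- function(epoch, cfg) {
  if (epoch < 0 || epoch > cfg@epochs)
    invalidArgument("epoch out of range")
  if (epoch < cfg@decayStartEpoch) return(cfg@lr0)
  span <- cfg@epochs - cfg@decayStartEpoch
  if (span == 0L) return(0)
  cfg@lr0 * (cfg@epochs - epoch) / span
}

toSigned <- function(p) 2 * p - 1      # [0,1] -> [-1,1]
toUnit <- function(s) 0.5 * s + 0.5    # [-1,1] -> [0,1]

#' Adversarial self-training on proximity-sampled patch pairs
#'
#' Fits the four sub-networks to the patch pairs of one stitched image.
#' Each step draws one (anomaly, normal) pair, updates both generators on
#' the joint objective — the two least-squares adversarial terms plus
#' `lambdaCons` times the content-consistency loss — and then updates each
#' discriminator on its own term (`dY` against the corrected anomaly patch,
#' `dX` against the synthesized normal patch). One epoch is one shuffled
#' traversal of the pair set. Fully deterministic given `cfg@seed` (weight
#' init, data order); training aborts with a diagnostic if any loss becomes
#' non-finite.
#'
#' @param trainingSet a non-empty [TrainingSet-class].
#' @param arch an [ArchitectureConfig-class] consistent with the patches.
#' @param cfg a [TrainingConfig-class].
#' @return list with `model` (a [CorrectionModel-class]) and `history`
#'   (data.frame of per-`logEvery` loss rows).
#' @export
trainSelfCorrection <- function(trainingSet, arch, cfg) {
  n <- nPairs(trainingSet)
  if (n == 0L) invalidArgument("training set is empty")
  if (dim(trainingSet@x[[1]])[3] != arch@inChannels)
    invalidArgument("patch channels do not match arch inChannels")
  if (trainingSet@patch != arch@patchSize)
    invalidArgument("patch size does not match arch patchSize")

  xs <- lapply(trainingSet@x, toSigned)
  ys <- lapply(trainingSet@y, toSigned)
  lam <- cfg@lambdaCons

  withSeed(cfg@seed, {
    gC <- buildCorrectionNetwork(arch, seed = sample.int(2^30, 1))
    gS <- buildCorrectionNetwork(arch, seed = sample.int(2^30, 1))
    dX <- buildDiscriminator(arch, seed = sample.int(2^30, 1))
    dY <- buildDiscriminator(arch, seed = sample.int(2^30, 1))
    stG_C <- adamInitState(gC); stG_S <- adamInitState(gS)
    stD_X <- adamInitState(dX); stD_Y <- adamInitState(dY)

    totalSteps <- cfg@epochs * n
    if (!is.na(cfg@maxSteps)) totalSteps <- min(totalSteps, cfg@maxSteps)
    hist <- vector("list", 0L)
    order <- integer(0)
    epoch <- -1L
    lr <- cfg@lr0

    for (step in seq_len(totalSteps)) {
      ep <- (step - 1L) %/% n
      if (ep != epoch) {
        epoch <- ep
        lr <- lrSchedule(epoch, cfg)
        order <- sample.int(n)
      }
      i <- order[(step - 1L) %% n + 1L]
      x <- xs[[i]]; y <- ys[[i]]

      ## ---- generator update -------------------------------------------
      fGCx <- netForward(gC, x)              # corrected anomaly patch
      fx <- fGCx$out
      fGSfx <- netForward(gS, fx)            # round trip x -> y' -> x''
      recX <- fGSfx$out
      fGSy <- netForward(gS, y)              # synthesized anomaly patch
      fy <- fGSy$out
      fGCfy <- netForward(gC, fy)            # round trip y -> x' -> y''
      recY <- fGCfy$out

      fDYfx <- netForward(dY, fx)
      fDXfy <- netForward(dX, fy)
      lAdvGC <- advGeneratorLoss(fDYfx$out)
      lAdvGS <- advGeneratorLoss(fDXfy$out)
      lConsX <- mean(abs(x - recX))
      lConsY <- mean(abs(y - recY))
      lCons <- lConsX + lConsY

      # adversarial gradients reach the generators through the (frozen)
      # discriminators' inputs
      dSy <- 2 * (fDYfx$out - 1) / length(fDYfx$out)
      dFxAdv <- netBackward(dY, fDYfx$caches, dSy)$dx
      dSx <- 2 * (fDXfy$out - 1) / length(fDXfy$out)
      dFyAdv <- netBackward(dX, fDXfy$caches, dSx)$dx

      dRecX <- lam * sign(recX - x) / length(recX)
      bGS1 <- netBackward(gS, fGSfx$caches, dRecX)
      dRecY <- lam * sign(recY - y) / length(recY)
      bGC1 <- netBackward(gC, fGCfy$caches, dRecY)

      bGC2 <- netBackward(gC, fGCx$caches, dFxAdv + bGS1$dx)
      bGS2 <- netBackward(gS, fGSy$caches, dFyAdv + bGC1$dx)

      gGC <- addGrads(bGC1$grads, bGC2$grads)
      gGS <- addGrads(bGS1$grads, bGS2$grads)
      up <- adamStep(gC, gGC, stG_C, lr, cfg@beta1, cfg@beta2)
      gC <- up$net; stG_C <- up$state
      up <- adamStep(gS, gGS, stG_S, lr, cfg@beta1, cfg@beta2)
      gS <- up$net; stG_S <- up$state

      ## ---- discriminator updates (detached fakes) ---------------------
      fDYy <- netForward(dY, y)
      fDYf <- netForward(dY, fx)
      lDY <- discriminatorLoss(fDYy$out, fDYf$out)
      gDY <- addGrads(
        netBackward(dY, fDYy$caches, 2 * (fDYy$out - 1) / length(fDYy$out))$grads,
        netBackward(dY, fDYf$caches, 2 * fDYf$out / length(fDYf$out))$grads)
      up <- adamStep(dY, gDY, stD_Y, lr, cfg@beta1, cfg@beta2)
      dY <- up$net; stD_Y <- up$state

      fDXx <- netForward(dX, x)
      fDXf <- netForward(dX, fy)
      lDX <- discriminatorLoss(fDXx$out, fDXf$out)
      gDX <- addGrads(
        netBackward(dX, fDXx$caches, 2 * (fDXx$out - 1) / length(fDXx$out))$grads,
        netBackward(dX, fDXf$caches, 2 * fDXf$out / length(fDXf$out))$grads)
      up <- adamStep(dX, gDX, stD_X, lr, cfg@beta1, cfg@beta2)
      dX <- up$net; stD_X <- up$state

      lTotal <- totalGeneratorObjective(lAdvGC, lAdvGS, lCons, lam)
      if (!all(is.finite(c(lAdvGC, lAdvGS, lCons, lDX, lDY))))
        stop(sprintf(
          "non-finite loss at step %d (advGC=%g advGS=%g cons=%g dX=%g dY=%g)",
          step, lAdvGC, lAdvGS, lCons, lDX, lDY))

      if (step %% cfg@logEvery == 0L || step == 1L || step == totalSteps)
        hist[[length(hist) + 1L]] <- data.frame(
          step = step, epoch = epoch, lr = lr, lAdvGC = lAdvGC,
          lAdvGS = lAdvGS, lCons = lCons, lTotal = lTotal, lDX = lDX,
          lDY = lDY)
    }

    model <- new("CorrectionModel", gC = gC, gS = gS, dX = dX, dY = dY,
                 arch = arch, seed = cfg@seed)
    history <- if (length(hist)) do.call(rbind, hist) else
      data.frame(step = integer(0), epoch = integer(0), lr = numeric(0),
                 lAdvGC = numeric(0), lAdvGS = numeric(0), lCons = numeric(0),
                 lTotal = numeric(0), lDX = numeric(0), lDY = numeric(0))
    list(model = model, history = history)
  })
}
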