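pkgVersion <- function()
  as.character(utils::packageVersion("stripecor"))

writeManifest <- function(dir, stage, params, inputs, outputs, seed) {
  # no timestamps: manifests must be bit-identical across reruns
  man <- list(stage = stage, package = "stripecor", version = pkgVersion(),
              seed = seed, params = params, inputs = inputs,
              outputs = outputs)
  path <- file.path(dir, paste0("manifest-", stage, ".json"))
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  path
}

demoDefaults <- function() {
  # the scaled-down end-to-end study conditions: a 128 x 128 phantom under
  # uniform amplitude-0.5 tile shading, 32 px patches, a slim network, and
  # 300 adversarial training steps
  list(
    synthesis = list(size = c(128L, 128L), n_cells = 12, n_fibers = 4,
                     background_level = 0.2, channels = 1,
                     stripe = list(kind = "uniform", tile_h = 64, tile_w = 64,
                                   amplitude = 0.5, angle_theta = 0,
                                   per_tile_jitter = 0)),
    sampling = list(patch = 32, n = 24, min_overlap = 0.3,
                    band_halfwidth = 6),
    arch = list(patch_size = 32, in_channels = 1, base_channels = 16,
                n_downsample = 2, n_residual_blocks = 2, disc_layers = 5),
    training = list(epochs = 25, decay_start_epoch = 13, max_steps = 300,
                    log_every = 10),
    correction = list(step = "half", blend = "feathered"))
}

mergeCfg <- function(defaults, override) {
  for (nm in names(override)) {
    defaults[[nm]] <- if (is.list(override[[nm]]) && is.list(defaults[[nm]]))
      mergeCfg(defaults[[nm]], override[[nm]]) else override[[nm]]
  }
  defaults
}

demoStripeROI <- function(stg) {
  # cross-stripe ROI spanning the interior tile boundary
  tw <- stg$synthesis$stripe$tile_w
  H <- stg$synthesis$size[1]
  ROI(c(round(H / 4), tw - 24, round(3 * H / 4), tw + 24),
      stripeAxis = "vertical")
}

#' Run the correction pipeline
#'
#' Stages: `synth` (phantom + degradation fixtures), `sample` (proximity
#' patch pairs), `train` (adversarial self-training), `correct`
#' (local-to-global sliding-window correction), `evaluate` (metrics
#' report), and `demo` — the full scaled-down loop on a seeded synthetic
#' fixture, writing a quality report. Every stage writes a JSON manifest of
#' its parameters, inputs, outputs and seed; manifests carry no timestamps
#' so a rerun with the same seed is bit-identical.
#'
#' @param cmd one of `"synth"`, `"sample"`, `"train"`, `"correct"`,
#'   `"evaluate"`, `"demo"`.
#' @param cfg a [RunConfig-class] (see [readRunConfig()]).
#' @return invisibly, a list of produced artifact paths and (for `demo` and
#'   `evaluate`) the computed metrics.
#' @export
runPipeline <- function(cmd, cfg) {
  cmd <- match.arg(cmd, c("synth", "sample", "train", "correct", "evaluate",
                          "demo"))
  dir.create(cfg@outputDir, recursive = TRUE, showWarnings = FALSE)
  switch(cmd,
    synth = stageSynth(cfg),
    sample = stageSample(cfg),
    train = stageTrain(cfg),
    correct = stageCorrect(cfg),
    evaluate = stageEvaluate(cfg),
    demo = stageDemo(cfg))
}

synthFromConfig <- function(stg, seed) {
  sy <- stg$synthesis
  clean <- generatePhantom(seed, sy$size, nCells = sy$n_cells,
                           nFibers = sy$n_fibers,
                           backgroundLevel = sy$background_level,
                           channels = sy$channels)
  sm <- StripeModel(kind = sy$stripe$kind, tileH = sy$stripe$tile_h,
                    tileW = sy$stripe$tile_w,
                    amplitude = sy$stripe$amplitude,
                    angleTheta = sy$stripe$angle_theta %||% 0,
                    perTileJitter = sy$stripe$per_tile_jitter %||% 0)
  field <- makeStripeField(sm, sy$size, seed = seed + 1L)
  degraded <- applyStripeField(clean, field)
  mask <- maskFromTileGrid(sy$size, sm@tileH, sm@tileW,
                           stg$sampling$band_halfwidth %||% 6,
                           angleTheta = sm@angleTheta)
  list(clean = clean, degraded = degraded, field = field, mask = mask,
       stripeModel = sm)
}

stageSynth <- function(cfg) {
  stg <- mergeCfg(demoDefaults(), cfg@stages)
  fx <- synthFromConfig(stg, cfg@seed)
  out <- file.path(cfg@outputDir, "synth")
  writeFixtureSet(out, fx$clean, fx$degraded, fx$field, fx$mask,
                  params = stg$synthesis)
  man <- writeManifest(cfg@outputDir, "synth", stg$synthesis, list(),
                       list(dir = "synth"), cfg@seed)
  invisible(list(dir = out, manifest = man))
}

stageSample <- function(cfg) {
  stg <- mergeCfg(demoDefaults(), cfg@stages)
  io <- stg$io
  img <- readImage(io$input)
  maskPx <- png::readPNG(io$mask)
  mask <- RegionMask(maskPx > 0.5, provenance = "user_mask")
  ts <- buildTrainingSet(img, mask, list(
    patch = stg$sampling$patch, n = stg$sampling$n,
    minOverlap = stg$sampling$min_overlap, stride = stg$sampling$stride,
    seed = cfg@seed))
  tsPath <- file.path(cfg@outputDir, "training-set.rds")
  saveRDS(ts, tsPath)
  idx <- list(patch = ts@patch,
              anomaly_origins = ts@xOrigins, normal_origins = ts@yOrigins,
              pair_distance = ts@pairDistance)
  idxPath <- file.path(cfg@outputDir, "pair-index.json")
  jsonlite::write_json(idx, idxPath, digits = NA)
  man <- writeManifest(cfg@outputDir, "sample", stg$sampling,
                       list(input = io$input, mask = io$mask),
                       list(training_set = "training-set.rds",
                            pair_index = "pair-index.json"), cfg@seed)
  invisible(list(trainingSet = tsPath, pairIndex = idxPath, manifest = man))
}

archFromConfig <- function(a) {
  ArchitectureConfig(patchSize = a$patch_size, inChannels = a$in_channels,
                     baseChannels = a$base_channels,
                     nDownsample = a$n_downsample %||% 2,
                     nResidualBlocks = a$n_residual_blocks,
                     discLayers = a$disc_layers %||% 5)
}

trainCfgFromConfig <- function(t, seed) {
  TrainingConfig(lr0 = t$lr0 %||% 2e-4, beta1 = t$beta1 %||% 0.5,
                 beta2 = t$beta2 %||% 0.999, epochs = t$epochs %||% 200,
                 decayStartEpoch = t$decay_start_epoch %||% 100,
                 lambdaCons = t$lambda_cons %||% 10,
                 logEvery = t$log_every %||% 10,
                 maxSteps = t$max_steps %||% NA, seed = seed)
}

stageTrain <- function(cfg) {
  stg <- mergeCfg(demoDefaults(), cfg@stages)
  ts <- readRDS(stg$io$input)
  arch <- archFromConfig(stg$arch)
  tc <- trainCfgFromConfig(stg$training, cfg@seed)
  fit <- trainSelfCorrection(ts, arch, tc)
  ckPath <- file.path(cfg@outputDir, "model.rds")
  saveCorrectionModel(fit$model, ckPath)
  histPath <- file.path(cfg@outputDir, "loss-history.csv")
  utils::write.csv(fit$history, histPath, row.names = FALSE)
  man <- writeManifest(cfg@outputDir, "train", stg$training,
                       list(training_set = stg$io$input),
                       list(model = "model.rds",
                            history = "loss-history.csv"), cfg@seed)
  invisible(list(model = ckPath, history = histPath, manifest = man))
}

stageCorrect <- function(cfg) {
  stg <- mergeCfg(demoDefaults(), cfg@stages)
  img <- readImage(stg$io$input)
  model <- readCorrectionModel(stg$io$model)
  plan <- planWindows(dim(img)[1:2], model@arch@patchSize,
                      stg$correction$step, stg$correction$blend)
  out <- correctWholeImage(img, model, plan)
  outPath <- stg$io$output %||% file.path(cfg@outputDir, "corrected.tif")
  writeImage(out, outPath, bitDepth = 16)
  man <- writeManifest(cfg@outputDir, "correct", stg$correction,
                       list(input = stg$io$input, model = stg$io$model),
                       list(output = basename(outPath)), cfg@seed)
  invisible(list(output = outPath, manifest = man))
}

stageEvaluate <- function(cfg) {
  stg <- mergeCfg(demoDefaults(), cfg@stages)
  img <- readImage(stg$io$input)
  ref <- if (!is.null(stg$io$reference)) readImage(stg$io$reference)
  rois <- lapply(stg$metrics$rois %||% list(), function(r)
    ROI(unlist(r$rect), r$stripe_axis %||% "vertical"))
  rep <- evaluateCorrection(img, ref, rois,
                            dataRange = stg$metrics$data_range %||% 1)
  repPath <- file.path(cfg@outputDir, "report.json")
  writeMetricsReport(rep, repPath)
  man <- writeManifest(cfg@outputDir, "evaluate", stg$metrics,
                       list(input = stg$io$input,
                            reference = stg$io$reference),
                       list(report = "report.json"), cfg@seed)
  invisible(list(report = repPath, reportObject = rep, manifest = man))
}

#' Scaled-down end-to-end demonstration run
#'
#' Generates a striped synthetic fixture, samples proximity pairs, trains
#' the model, corrects the whole image, and reports PSNR / SSIM / ICV
#' before and after correction. Used both as a smoke test of the full
#' pipeline and as the reproducible self-correction experiment.
#'
#' @param cfg a [RunConfig-class]; stage settings override the demo
#'   defaults.
#' @return invisibly, list with `report` (named numerics) and artifact
#'   paths.
#' @export
stageDemo <- function(cfg) {
  stg <- mergeCfg(demoDefaults(), cfg@stages)
  fx <- synthFromConfig(stg, cfg@seed)
  ts <- buildTrainingSet(fx$degraded, fx$mask, list(
    patch = stg$sampling$patch, n = stg$sampling$n,
    minOverlap = stg$sampling$min_overlap, seed = cfg@seed,
    tileH = fx$stripeModel@tileH, tileW = fx$stripeModel@tileW))
  arch <- archFromConfig(stg$arch)
  tc <- trainCfgFromConfig(stg$training, cfg@seed)
  fit <- trainSelfCorrection(ts, arch, tc)
  plan <- planWindows(dim(fx$degraded)[1:2], arch@patchSize,
                      stg$correction$step, stg$correction$blend)
  corrected <- correctWholeImage(fx$degraded, fit$model, plan)

  roi <- demoStripeROI(stg)
  psnrStriped <- psnr(fx$degraded, fx$clean)
  psnrCorrected <- psnr(corrected, fx$clean)
  report <- list(
    seed = cfg@seed,
    n = dim(fx$clean@pixels)[1],
    steps = max(fit$history$step),
    psnr_striped = psnrStriped,
    psnr_corrected = psnrCorrected,
    psnr_improved = psnrCorrected > psnrStriped,
    ssim_striped = ssim(fx$degraded, fx$clean),
    ssim_corrected = ssim(corrected, fx$clean),
    icv_clean = icv(fx$clean, roi),
    icv_striped = icv(fx$degraded, roi),
    icv_corrected = icv(corrected, roi),
    icv_improved = icv(corrected, roi) > icv(fx$degraded, roi),
    l_cons_initial = fit$history$lCons[1],
    l_cons_final = fit$history$lCons[nrow(fit$history)])
  out <- file.path(cfg@outputDir, "demo")
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  writeFixtureSet(file.path(out, "fixture"), fx$clean, fx$degraded,
                  fx$field, fx$mask, params = stg$synthesis)
  writeImage(corrected, file.path(out, "corrected.tif"), bitDepth = 16)
  utils::write.csv(fit$history, file.path(out, "loss-history.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeManifest(cfg@outputDir, "demo",
                stg[c("synthesis", "sampling", "arch", "training",
                      "correction")],
                list(), list(dir = "demo"), cfg@seed)
  invisible(list(report = report, dir = out, model = fit$model,
                 history = fit$history, fixture = fx, corrected = corrected))
}
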