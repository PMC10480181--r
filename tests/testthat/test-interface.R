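test_that("image IO maps full-scale codes to 1.0 and round-trips 16-bit", {
  d <- withr::local_tempdir()
  # full-scale 8-bit and 16-bit pixels read back as exactly 1.0
  p8 <- file.path(d, "a8.png")
  png::writePNG(matrix(c(0, 1, 0.5, 1), 2, 2), p8)
  img8 <- readImage(p8)
  expect_equal(max(pixels(img8)), 1.0)

  ph <- smallPhantom(seed = 6, size = c(64, 64))
  p16 <- file.path(d, "a16.tif")
  writeImage(ph, p16, bitDepth = 16)
  back <- readImage(p16)
  # writing the quantized raster again is lossless
  p16b <- file.path(d, "b16.tif")
  writeImage(back, p16b, bitDepth = 16)
  expect_identical(pixels(readImage(p16b)), pixels(back))
  # quantization error bounded by half a 16-bit code
  expect_lt(max(abs(pixels(back) - pixels(ph))), 1 / 65535)
})

test_that("quantization is round-half-even with clipped endpoints", {
  ns <- asNamespace("stripecor")
  expect_equal(ns$quantizeUnit(0.5, 8) * 255, 128)  # 127.5 rounds to even 128
  expect_equal(ns$quantizeUnit(0, 8), 0)
  expect_equal(ns$quantizeUnit(1, 8) * 255, 255)
  # values outside [0,1] are clipped before quantization on write
  r <- ImageRaster(array(c(-0.2, 0.4, 1.7, 0.1), dim = c(2, 2, 1)))
  expect_true(all(pixels(r) >= 0 & pixels(r) <= 1))
})

test_that("unsupported formats are rejected with the offending path", {
  d <- withr::local_tempdir()
  rgba <- array(runif(16 * 16 * 4), dim = c(16, 16, 4))
  p <- file.path(d, "rgba.png")
  png::writePNG(rgba, p)
  expect_error(readImage(p), "alpha")
  expect_error(readImage(file.path(d, "missing.tif")), "not found")
  bad <- file.path(d, "x.bmp")
  writeLines("x", bad)
  expect_error(readImage(bad), "unsupported")
})

test_that("run configurations reject unknown keys with a field path", {
  cfg <- asRunConfig(list(seed = 3, output_dir = tempfile(),
                          sampling = list(patch = 16, n = 4)))
  expect_s4_class(cfg, "RunConfig")
  expect_error(asRunConfig(list(seed = 1, bogus = 2)),
               class = "stripecor_config_error")
  err <- tryCatch(asRunConfig(list(training = list(lr = 1))),
                  error = function(e) conditionMessage(e))
  expect_match(err, "training.lr")
})

test_that("demo runs are deterministic and self-describing", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  # a very short run: determinism holds at any step count
  stages <- list(
    synthesis = list(size = c(96, 96), n_cells = 6, n_fibers = 2,
                     stripe = list(tile_h = 48, tile_w = 48)),
    sampling = list(patch = 16, n = 6, band_halfwidth = 4),
    arch = list(patch_size = 16, base_channels = 4, n_residual_blocks = 1,
                disc_layers = 3),
    training = list(max_steps = 8, epochs = 4, decay_start_epoch = 2))
  r1 <- suppressMessages(runPipeline("demo",
    new("RunConfig", stages = stages, seed = 7L, outputDir = d1,
        verbosity = 0L)))
  r2 <- suppressMessages(runPipeline("demo",
    new("RunConfig", stages = stages, seed = 7L, outputDir = d2,
        verbosity = 0L)))
  expect_identical(r1$report, r2$report)
  # manifests and reports are byte-identical across reruns
  expect_identical(readLines(file.path(d1, "demo", "report.json")),
                   readLines(file.path(d2, "demo", "report.json")))
  expect_identical(readLines(file.path(d1, "manifest-demo.json")),
                   readLines(file.path(d2, "manifest-demo.json")))
  # fixture artifacts exist
  expect_true(file.exists(file.path(d1, "demo", "fixture", "clean.tif")))
  expect_true(file.exists(file.path(d1, "demo", "fixture", "mask.png")))
  expect_true(file.exists(file.path(d1, "demo", "corrected.tif")))
  # the quality report carries the expected fields
  expect_true(all(c("psnr_striped", "psnr_corrected", "icv_striped",
                    "icv_corrected", "l_cons_initial", "l_cons_final") %in%
                    names(r1$report)))
})

test_that("staged pipeline chains through files on disk", {
  d <- withr::local_tempdir()
  stages <- list(
    synthesis = list(size = c(96, 96), n_cells = 6, n_fibers = 2,
                     stripe = list(tile_h = 48, tile_w = 48)),
    sampling = list(patch = 16, n = 6, band_halfwidth = 4),
    arch = list(patch_size = 16, base_channels = 4, n_residual_blocks = 1,
                disc_layers = 3),
    training = list(max_steps = 6, epochs = 3, decay_start_epoch = 2))
  base <- new("RunConfig", stages = stages, seed = 5L, outputDir = d,
              verbosity = 0L)
  runPipeline("synth", base)
  expect_true(file.exists(file.path(d, "synth", "degraded.tif")))

  s2 <- base
  s2@stages$io <- list(input = file.path(d, "synth", "degraded.tif"),
                       mask = file.path(d, "synth", "mask.png"))
  suppressMessages(runPipeline("sample", s2))
  expect_true(file.exists(file.path(d, "training-set.rds")))
  idx <- jsonlite::read_json(file.path(d, "pair-index.json"))
  expect_equal(idx$patch[[1]], 16)

  s3 <- base
  s3@stages$io <- list(input = file.path(d, "training-set.rds"))
  runPipeline("train", s3)
  expect_true(file.exists(file.path(d, "model.rds")))
  expect_true(file.exists(file.path(d, "loss-history.csv")))

  s4 <- base
  s4@stages$io <- list(input = file.path(d, "synth", "degraded.tif"),
                       model = file.path(d, "model.rds"),
                       output = file.path(d, "corrected.tif"))
  runPipeline("correct", s4)
  expect_true(file.exists(file.path(d, "corrected.tif")))

  s5 <- base
  s5@stages$io <- list(input = file.path(d, "corrected.tif"),
                       reference = file.path(d, "synth", "clean.tif"))
  s5@stages$metrics <- list(rois = list(list(rect = c(24, 24, 72, 72))))
  res <- runPipeline("evaluate", s5)
  expect_true(file.exists(file.path(d, "report.json")))
  expect_s4_class(res$reportObject, "MetricsReport")
  expect_false(is.na(res$reportObject@ssim))
})
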