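test_that("window planning enumerates clamped origins", {
  plan <- planWindows(c(512, 512), 256, 128)
  expect_equal(sort(unique(plan@origins[, 1])), c(0L, 128L, 256L))
  expect_equal(nrow(plan@origins), 9)

  exact <- planWindows(c(64, 64), 64, 32)
  expect_equal(unname(exact@origins), matrix(c(0L, 0L), 1))

  # default step is half the patch size
  expect_equal(planWindows(c(512, 512), 256, "half")@step, 128L)
  expect_equal(resolveStep(256, "100"), 100L)

  # non-divisible step: final origin clamped, coverage complete
  p2 <- planWindows(c(300, 300), 128, 100)
  expect_equal(sort(unique(p2@origins[, 1])), c(0L, 100L, 172L))
})

test_that("blend weights are positive with a unit plateau", {
  u <- blendWeights(32, "uniform")
  expect_true(all(u == 1))
  f <- blendWeights(32, "feathered")
  expect_equal(f[16, 16], 1)
  expect_true(all(f > 0))
  expect_equal(f[1, 16], 1 / 8)  # edge of the P/4 = 8 px ramp
})

test_that("accumulated weights match a brute-force shifted sum", {
  plan <- planWindows(c(96, 96), 32, 20)
  acc <- matrix(0, 96, 96)
  for (k in seq_len(nrow(plan@origins))) {
    r <- plan@origins[k, 1]; c <- plan@origins[k, 2]
    acc[(r + 1):(r + 32), (c + 1):(c + 32)] <-
      acc[(r + 1):(r + 32), (c + 1):(c + 32)] + plan@weightMap
  }
  expect_true(all(acc > 0))
  # the oracle accumulation is what correctWholeImage divides by: a
  # pass-through generator must therefore reproduce the input exactly
  img <- dyadicRaster(smallPhantom(seed = 8, size = c(96, 96)))
  out <- correctWholeImage(img, function(p) p, plan)
  expect_identical(pixels(out), pixels(img))
})

test_that("identity generator reproduces the input for every plan", {
  for (sz in list(c(96, 96), c(192, 160), c(512, 512))) {
    img <- dyadicRaster(
      generatePhantom(sz[1] + sz[2], sz, nCells = 8, nFibers = 2,
                      backgroundLevel = 0.15))
    # the 100 px step convention needs P > 100 for full coverage
    for (pw in list(list(64, "half"), list(128, "half"), list(128, "100"))) {
      plan <- planWindows(sz, pw[[1]], pw[[2]])
      out <- correctWholeImage(img, function(p) p, plan)
      expect_identical(pixels(out), pixels(img))
    }
  }
  expect_error(planWindows(c(256, 256), 64, "100"),
               class = "stripecor_invalid_argument")
})

test_that("constant generators yield constant output despite overlap", {
  img <- smallPhantom(seed = 2, size = c(96, 96))
  plan <- planWindows(c(96, 96), 32, 24)
  out <- correctWholeImage(img, function(p) p * 0 + 0.2, plan)
  expect_true(all(abs(pixels(out) - 0.6) < 1e-12))  # 0.2 in [-1,1] is 0.6
})

test_that("merging equals the per-pixel weighted mean over covering windows", {
  img <- smallPhantom(seed = 9, size = c(96, 96))
  plan <- planWindows(c(96, 96), 32, 20)
  # an arbitrary, deterministic position-dependent "generator"
  gen <- function(p) tanh(p + mean(p))
  out <- correctWholeImage(img, gen, plan)
  ns <- asNamespace("stripecor")
  x <- ns$toSigned(pixels(img))
  num <- array(0, dim = dim(x)); den <- matrix(0, 96, 96)
  w <- plan@weightMap
  for (k in seq_len(nrow(plan@origins))) {
    r <- plan@origins[k, 1]; c <- plan@origins[k, 2]
    rs <- (r + 1):(r + 32); cs <- (c + 1):(c + 32)
    num[rs, cs, ] <- num[rs, cs, , drop = FALSE] +
      gen(x[rs, cs, , drop = FALSE]) * as.vector(w)
    den[rs, cs] <- den[rs, cs] + w
  }
  oracle <- pmin(pmax(ns$toUnit(num / as.vector(den)), 0), 1)
  expect_equal(pixels(out), oracle, tolerance = 1e-15)
})

test_that("rasters smaller than the patch are padded and cropped back", {
  img <- dyadicRaster(ImageRaster(matrix(runif(40 * 48), 40, 48)))
  plan <- planWindows(c(40, 48), 64, 32)
  out <- correctWholeImage(img, function(p) p, plan)
  expect_equal(dim(pixels(out)), c(40, 48, 1))
  expect_identical(pixels(out), pixels(img))
})

test_that("channel mismatch against a trained model is rejected", {
  arch <- tinyArch(P = 16, C = 1)
  model <- new("CorrectionModel", gC = buildCorrectionNetwork(arch, 1),
               gS = buildCorrectionNetwork(arch, 2),
               dX = buildDiscriminator(arch, 3),
               dY = buildDiscriminator(arch, 4), arch = arch, seed = 1L)
  img <- smallPhantom(seed = 1, size = c(64, 64), channels = 3)
  plan <- planWindows(c(64, 64), 16, 8)
  expect_error(correctWholeImage(img, model, plan),
               class = "stripecor_invalid_argument")
})
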