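test_that("phantom generation is deterministic and honours an empty spec", {
  a <- generatePhantom(7, c(64, 64), nCells = 5, nFibers = 3)
  b <- generatePhantom(7, c(64, 64), nCells = 5, nFibers = 3)
  expect_identical(pixels(a), pixels(b))

  z <- generatePhantom(1, c(64, 64), nCells = 0, nFibers = 0,
                       backgroundLevel = 0)
  expect_true(all(pixels(z) == 0))

  expect_error(generatePhantom(1, c(32, 64)), class = "stripecor_invalid_argument")
})

test_that("non-overlapping blobs yield one connected component per cell", {
  skip_if_not_installed("EBImage")
  ph <- generatePhantom(1, c(256, 256), nCells = 20, nFibers = 0,
                        backgroundLevel = 0, nonOverlapping = TRUE)
  lab <- EBImage::bwlabel(pixels(ph)[, , 1] > 0.1)
  expect_equal(max(lab), 20)
})

test_that("stripe fields honour their closed forms", {
  # zero-depth shading: field identically one
  f0 <- makeStripeField(StripeModel("uniform", 32, 32, 0), c(64, 64))
  expect_true(all(fieldValues(f0) == 1))

  # grid field is exactly the outer product of its two 1-d profiles
  fg <- makeStripeField(StripeModel("grid", 32, 16, 0.4), c(64, 64))
  prof <- function(idx, tile, a) {
    t <- ((idx - 0.5) %% tile) / tile
    (1 - a) + a * (0.5 - 0.5 * cospi(2 * t))
  }
  oracle <- outer(prof(1:64, 32, 0.4), prof(1:64, 16, 0.4))
  expect_equal(fieldValues(fg), oracle, tolerance = 1e-14)

  # oblique at theta = 0 degenerates to the uniform field bit-for-bit
  fu <- makeStripeField(StripeModel("uniform", 32, 32, 0.5), c(64, 96))
  fo <- makeStripeField(StripeModel("oblique", 32, 32, 0.5, angleTheta = 0),
                        c(64, 96))
  expect_identical(fieldValues(fu), fieldValues(fo))

  # non-uniform jitter is seeded and reproducible
  n1 <- makeStripeField(StripeModel("non_uniform", 32, 32, 0.5,
                                    perTileJitter = 0.3), c(96, 96), seed = 4)
  n2 <- makeStripeField(StripeModel("non_uniform", 32, 32, 0.5,
                                    perTileJitter = 0.3), c(96, 96), seed = 4)
  expect_identical(fieldValues(n1), fieldValues(n2))
})

test_that("admissible stripe models always render positive bounded fields", {
  set.seed(11)
  for (i in 1:25) {
    kind <- sample(c("uniform", "non_uniform", "grid", "oblique"), 1)
    m <- StripeModel(kind, sample(8:40, 1), sample(8:40, 1),
                     runif(1, 0, 0.95),
                     angleTheta = if (kind == "oblique") runif(1, -30, 30) else 0,
                     perTileJitter = runif(1, 0, 0.5))
    f <- makeStripeField(m, c(80, 80), seed = i)
    expect_gt(min(fieldValues(f)), 0)
    expect_lte(max(fieldValues(f)), 1)
  }
})

test_that("multiplicative degradation is invertible where unclipped", {
  fx <- uniformStripeFixture(seed = 3, size = c(96, 96), tile = 48)
  unit <- makeStripeField(StripeModel("uniform", 48, 48, 0), c(96, 96))
  expect_identical(pixels(applyStripeField(fx$clean, unit)),
                   pixels(fx$clean))

  v <- fieldValues(fx$field)
  recovered <- pixels(fx$degraded)[, , 1] / v
  unclipped <- pixels(fx$clean)[, , 1] * v <= 1
  expect_lt(max(abs((recovered - pixels(fx$clean)[, , 1])[unclipped])), 1e-6)

  wrong <- makeStripeField(StripeModel("uniform", 48, 48, 0.2), c(48, 96))
  expect_error(applyStripeField(fx$clean, wrong),
               class = "stripecor_invalid_argument")
})

test_that("constant-image ICV under a known uniform field matches the field", {
  # on a constant image the ROI statistics are those of the field itself
  img <- ImageRaster(array(0.5, dim = c(64, 64, 1)))
  f <- makeStripeField(StripeModel("uniform", 32, 32, 0.5), c(64, 64))
  deg <- applyStripeField(img, f)
  roi <- ROI(c(0, 0, 64, 64))
  v <- 0.5 * fieldValues(f)
  expect_equal(icv(deg, roi), mean(v) / sqrt(mean((v - mean(v))^2)),
               tolerance = 1e-12)
})

test_that("increasing stripe amplitude strictly decreases cross-stripe ICV", {
  ph <- smallPhantom(seed = 5, size = c(96, 96), nCells = 4, nFibers = 1)
  roi <- ROI(c(24, 16, 72, 80))
  vals <- vapply(c(0.2, 0.4, 0.6, 0.8), function(a) {
    f <- makeStripeField(StripeModel("uniform", 48, 48, a), c(96, 96))
    icv(applyStripeField(ph, f), roi)
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("out-of-focus artifact honours identity and constant closure", {
  ph <- smallPhantom(seed = 2)
  noop <- ArtifactSpec("out_of_focus", "rect", c(16, 16, 48, 48),
                       blurSigma = 0, attenuation = 1)
  expect_identical(pixels(applyArtifact(ph, noop)), pixels(ph))

  const <- ImageRaster(array(0.6, dim = c(96, 96, 1)))
  spec <- ArtifactSpec("out_of_focus", "rect", c(24, 24, 56, 56),
                       blurSigma = 2, attenuation = 0.7)
  out <- applyArtifact(const, spec)
  inside <- pixels(out)[25:56, 25:56, 1]
  expect_equal(mean(inside), 0.7 * 0.6, tolerance = 1e-10)
  # feathering acts outside the region only, and decays within 8 px
  expect_equal(pixels(out)[1, 1, 1], 0.6)

  bad <- ArtifactSpec("out_of_focus", "rect", c(24, 24, 200, 56))
  expect_error(applyArtifact(const, bad), class = "stripecor_invalid_argument")
})

test_that("scanning fringe preserves the mean over whole periods", {
  const <- ImageRaster(array(0.5, dim = c(96, 96, 1)))
  spec <- ArtifactSpec("scan_fringe", "rect", c(8, 8, 72, 72),
                       fringePeriod = 8, fringeAmplitude = 0.3, seed = 9)
  out <- applyArtifact(const, spec)
  # rows 8..71: 64 rows = 8 whole periods; the sinusoid integrates to zero
  expect_equal(mean(pixels(out)[9:72, 9:72, 1]), 0.5, tolerance = 1e-10)
  # outside the region the image is untouched
  expect_identical(pixels(out)[1:8, , 1], pixels(const)[1:8, , 1])
})

test_that("bubble artifact darkens a continuous rim inside the disk", {
  const <- ImageRaster(array(0.8, dim = c(96, 96, 1)))
  spec <- ArtifactSpec("bubble", "disk", c(48, 48, 24), rimWidth = 6,
                       depth = 0.5, seed = 1)
  out <- applyArtifact(const, spec)
  p <- pixels(out)[, , 1]
  # rim centre (rho ~ R - rimWidth/2) is the darkest ring
  rim <- p[48 + 1, 48 + 1 + 21]
  expect_lt(rim, 0.8 * (1 - 0.5 * 0.9))
  # outside the disk untouched
  expect_equal(p[1, 1], 0.8)
  # field is continuous: no jump larger than the discrete gradient bound
  expect_lt(max(abs(diff(p[49, ]))), 0.25)
})
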