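test_that("tile-grid masks match a brute-force distance-to-line scan", {
  m <- maskFromTileGrid(c(256, 256), 128, 128, 4)
  # oracle: pixels within 4 px of any line x/y in {0, 128, 256}
  lines <- c(0, 128, 256)
  oracle <- matrix(FALSE, 256, 256)
  for (r in 0:255) for (c in 0:255) {
    oracle[r + 1, c + 1] <- min(abs(c - lines)) <= 4 || min(abs(r - lines)) <= 4
  }
  expect_identical(maskMatrix(m), oracle)
})

test_that("tile-grid mask rejects degenerate bands and is 360-degree periodic", {
  expect_error(maskFromTileGrid(c(64, 64), 16, 16, 8),
               class = "stripecor_invalid_argument")
  a <- maskFromTileGrid(c(96, 96), 32, 32, 3, angleTheta = 0)
  b <- maskFromTileGrid(c(96, 96), 32, 32, 3, angleTheta = 360)
  expect_identical(maskMatrix(a), maskMatrix(b))
})

test_that("anomaly sampling matches exhaustive origin enumeration", {
  # 4-px vertical stripe at x = 32 on a 64 x 64 raster
  mask <- matrix(FALSE, 64, 64)
  mask[, 31:34] <- TRUE
  img <- smallPhantom(seed = 1, size = c(64, 64))
  # more patches requested than exist: all admissible origins are returned,
  # flagged as truncated
  expect_warning(
    rs <- sampleAnomalyPatches(img, RegionMask(mask), patch = 16, n = 1000,
                               minOverlap = 0.1, seed = 2, stride = 4),
    "admissible")
  expect_true(rs$truncated)
  oracle <- bruteAdmissibleOrigins(mask, 16, 4, 0.1)
  got <- rs$origins[order(rs$origins[, 1], rs$origins[, 2]), ]
  exp <- oracle[order(oracle[, 1], oracle[, 2]), ]
  expect_equal(unname(got), unname(exp))
})

test_that("an all-false mask yields an empty sample with a warning", {
  img <- smallPhantom(seed = 1, size = c(64, 64))
  expect_warning(
    rs <- sampleAnomalyPatches(img, RegionMask(matrix(FALSE, 64, 64)),
                               16, 5, 0.3, 1),
    "no admissible")
  expect_equal(nrow(rs$origins), 0)
  expect_true(rs$truncated)
})

test_that("full-overlap requirement forces the unique covering origin", {
  mask <- matrix(FALSE, 64, 64)
  mask[17:32, 25:40] <- TRUE  # exactly one 16 x 16 block at origin (16, 24)
  img <- smallPhantom(seed = 1, size = c(64, 64))
  expect_warning(
    rs <- sampleAnomalyPatches(img, RegionMask(mask), 16, 10,
                               minOverlap = 1.0, seed = 1, stride = 4),
    "admissible")
  expect_equal(unname(rs$origins), matrix(c(16L, 24L), 1))
})

test_that("nearest-normal pairing equals brute-force minimization", {
  set.seed(99)
  for (rep in 1:20) {
    H <- 64; P <- 16; stride <- 4
    mask <- matrix(FALSE, H, H)
    # random stripe band plus a random block
    x0 <- sample(10:50, 1)
    mask[, x0:min(H, x0 + sample(2:6, 1))] <- TRUE
    r0 <- sample(1:48, 1); c0 <- sample(1:48, 1)
    mask[r0:(r0 + 7), c0:(c0 + 7)] <- TRUE
    img <- ImageRaster(matrix(runif(H * H), H, H))
    suppressWarnings(
      rs <- sampleAnomalyPatches(img, RegionMask(mask), P, 6,
                                 minOverlap = 0.2, seed = rep, stride = stride))
    if (nrow(rs$origins) == 0) next
    pairs <- pairNearestNormal(rs$origins, img, RegionMask(mask), P, stride)
    lat <- bruteAdmissibleOrigins(!mask, P, stride, 1.0)  # zero anomaly pixels
    for (i in seq_along(pairs)) {
      pp <- pairs[[i]]
      # normal patch carries no anomaly pixels
      no <- pp@normalOrigin
      expect_false(any(mask[(no[1] + 1):(no[1] + P), (no[2] + 1):(no[2] + P)]))
      d2 <- (lat[, 1] - pp@anomalyOrigin[1])^2 + (lat[, 2] - pp@anomalyOrigin[2])^2
      expect_equal(pp@pairDistance, sqrt(min(d2)))
    }
  }
})

test_that("equidistant normal candidates resolve to the smaller column", {
  # anomaly block in the middle; normal regions symmetric left/right
  mask <- matrix(FALSE, 32, 96)
  mask[, 41:56] <- TRUE
  img <- ImageRaster(matrix(runif(32 * 96), 32, 96))
  pairs <- pairNearestNormal(matrix(c(0L, 40L), 1), img, RegionMask(mask),
                             patch = 16, stride = 8)
  # candidates at columns 24 (left) and 56 (right) are both 16 away
  expect_equal(pairs[[1]]@normalOrigin[2], 24L)
})

test_that("artifact-mode pairing picks normals outside the disk", {
  spec <- ArtifactSpec("bubble", "disk", c(48, 48, 18), rimWidth = 4,
                       depth = 0.3)
  mask <- maskFromArtifact(spec, c(96, 96))
  img <- smallPhantom(seed = 4, size = c(96, 96))
  suppressWarnings(
    rs <- sampleAnomalyPatches(img, mask, 16, 4, minOverlap = 0.6, seed = 1))
  pairs <- pairNearestNormal(rs$origins, img, mask, 16)
  lat <- bruteAdmissibleOrigins(!maskMatrix(mask), 16, 4, 1.0)
  for (pp in pairs) {
    expect_false(any(maskMatrix(mask)[(pp@normalOrigin[1] + 1):(pp@normalOrigin[1] + 16),
                                      (pp@normalOrigin[2] + 1):(pp@normalOrigin[2] + 16)]))
    d2 <- (lat[, 1] - pp@anomalyOrigin[1])^2 + (lat[, 2] - pp@anomalyOrigin[2])^2
    expect_equal(pp@pairDistance, sqrt(min(d2)))
  }
})

test_that("training sets reflect multiplicative attenuation at the set level", {
  fx <- uniformStripeFixture(seed = 6, size = c(128, 128), tile = 64)
  mask <- maskFromTileGrid(c(128, 128), 64, 64, 6)
  ts <- suppressMessages(buildTrainingSet(fx$degraded, mask,
    list(patch = 32, n = 20, minOverlap = 0.3, seed = 3,
         tileH = 64, tileW = 64)))
  expect_gt(nPairs(ts), 0)
  mx <- mean(vapply(ts@x, mean, numeric(1)))
  my <- mean(vapply(ts@y, mean, numeric(1)))
  expect_lte(mx, my)  # shaded patches are dimmer on average
})

test_that("degenerate training-set requests are rejected or vacuous", {
  fx <- uniformStripeFixture(seed = 1, size = c(128, 128))
  mask <- maskFromTileGrid(c(128, 128), 64, 64, 6)
  expect_error(
    buildTrainingSet(fx$degraded, RegionMask(matrix(FALSE, 128, 128)),
                     list(patch = 32, n = 5)),
    class = "stripecor_invalid_argument")
  expect_error(
    buildTrainingSet(fx$degraded, mask,
                     list(patch = 64, n = 5, tileH = 64, tileW = 64)),
    class = "stripecor_invalid_argument")
  empty <- buildTrainingSet(fx$degraded, mask, list(patch = 32, n = 0))
  expect_s4_class(empty, "TrainingSet")
  expect_equal(nPairs(empty), 0)
})
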