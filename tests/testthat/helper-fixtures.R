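# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

smallPhantom <- function(seed = 1, size = c(96, 96), nCells = 6, nFibers = 2,
                         background = 0.2, channels = 1) {
  generatePhantom(seed, size, nCells = nCells, nFibers = nFibers,
                  backgroundLevel = background, channels = channels)
}

uniformStripeFixture <- function(seed = 1, size = c(128, 128), tile = 64,
                                 amplitude = 0.5) {
  clean <- generatePhantom(seed, size, nCells = 12, nFibers = 4,
                           backgroundLevel = 0.2, channels = 1)
  field <- makeStripeField(StripeModel("uniform", tile, tile, amplitude),
                           size)
  list(clean = clean, field = field,
       degraded = applyStripeField(clean, field))
}

# quantize raster values to a dyadic grid (exact in binary floating point)
dyadicRaster <- function(img, bits = 10) {
  m <- 2^bits
  ImageRaster(round(pixels(img) * m) / m, valueRange = valueRange(img))
}

# brute-force anomaly-fraction scan over a full origin lattice
bruteAdmissibleOrigins <- function(mask, P, stride, minOverlap) {
  H <- nrow(mask); W <- ncol(mask)
  rs <- sort(unique(c(seq(0, H - P, by = stride), H - P)))
  cs <- sort(unique(c(seq(0, W - P, by = stride), W - P)))
  out <- NULL
  for (r in rs) for (c in cs) {
    frac <- mean(mask[(r + 1):(r + P), (c + 1):(c + P)])
    if (frac >= minOverlap - 1e-9) out <- rbind(out, c(r, c))
  }
  out
}

tinyArch <- function(P = 16, C = 1, base = 4, res = 1, disc = 3) {
  ArchitectureConfig(patchSize = P, inChannels = C, baseChannels = base,
                     nDownsample = 2, nResidualBlocks = res,
                     discLayers = disc)
}
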