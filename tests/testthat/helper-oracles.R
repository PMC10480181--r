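# direct transcription of the SSIM formula: explicit loop over all 11 x 11
# windows with Gaussian weights; independent of the package's band-matrix path
ssimLoopOracle <- function(a, b, dataRange = 1) {
  k1d <- local({
    g <- exp(-(seq(-5, 5))^2 / (2 * 1.5^2)); g / sum(g)
  })
  K <- outer(k1d, k1d)
  C1 <- (0.01 * dataRange)^2; C2 <- (0.03 * dataRange)^2
  H <- nrow(a); W <- ncol(a)
  vals <- c()
  for (i in 1:(H - 10)) for (j in 1:(W - 10)) {
    wa <- a[i:(i + 10), j:(j + 10)]
    wb <- b[i:(i + 10), j:(j + 10)]
    ma <- sum(K * wa); mb <- sum(K * wb)
    va <- sum(K * wa^2) - ma^2; vb <- sum(K * wb^2) - mb^2
    cab <- sum(K * wa * wb) - ma * mb
    vals <- c(vals, ((2 * ma * mb + C1) * (2 * cab + C2)) /
                ((ma^2 + mb^2 + C1) * (va + vb + C2)))
  }
  mean(vals)
}
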