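#' @useDynLib stripecor, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats rnorm runif sd
NULL

# Run `code` under a private RNG stream seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All package randomness goes through this;
# nothing touches the global stream.
withSeed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(code)
}

clipRange <- function(x, lo, hi) {
  x[x < lo] <- lo
  x[x > hi] <- hi
  x
}

# Coerce H x W (x C) numeric data to a 3-d array.
asPixelArray <- function(x) {
  if (is.matrix(x)) x <- array(x, dim = c(dim(x), 1L))
  if (!is.array(x) || length(dim(x)) != 3L)
    stop("pixel data must be an H x W x C array or an H x W matrix")
  storage.mode(x) <- "double"
  x
}

invalidArgument <- function(msg) {
  stop(errorCondition(msg, class = c("stripecor_invalid_argument", "error")))
}

# Separable Gaussian blur with reflected boundaries; radius = ceil(3*sigma).
gaussianBlurMatrix <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k <- k / sum(k)
  pad <- function(idx, n) {
    # reflect-101 style mirroring of out-of-range indices
    idx[idx < 1L] <- 2L - idx[idx < 1L]
    idx[idx > n] <- 2L * n - idx[idx > n]
    idx
  }
  H <- nrow(m); W <- ncol(m)
  rp <- pad(seq(1L - r, H + r), H)
  cp <- pad(seq(1L - r, W + r), W)
  mp <- m[rp, cp, drop = FALSE]
  # band matrices performing 'valid' 1-d convolution along each axis
  Kh <- matrix(0, H, H + 2L * r)
  for (i in seq_len(H)) Kh[i, i:(i + 2L * r)] <- k
  Kw <- matrix(0, W, W + 2L * r)
  for (i in seq_len(W)) Kw[i, i:(i + 2L * r)] <- k
  Kh %*% mp %*% t(Kw)
}
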