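# Internal helpers: deterministic seed derivation and scoped RNG use.

# Derive a 31-bit sub-seed from a base seed and a stream of small integers /
# strings. Stages, subjects, folds, bands and classes each get independent,
# reproducible streams so pipeline stages can be rerun in isolation.
deriveSeed <- function(seed, ...) {
  parts <- unlist(lapply(list(...), function(p) {
    if (is.character(p)) utf8ToInt(p) else as.integer(p)
  }))
  h <- as.double(seed %% 2147483647L)
  for (p in parts) h <- (h * 69069 + as.double(p) * 2654435761 + 1) %% 2147483647
  as.integer(h)
}

# Evaluate expr with a locally-set RNG seed, restoring global RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Zero-phase Butterworth bandpass applied per channel (rows).
butterBandpass <- function(mat, fs, low, high, order = 4L) {
  ny <- fs / 2
  stopifnot(low > 0, high > low, high < ny)
  flt <- signal::butter(order, c(low, high) / ny, type = "pass")
  t(apply(mat, 1L, function(ch) signal::filtfilt(flt, ch)))
}

# Zero-phase FIR filtering via FFT convolution with mirrored edge padding;
# b must be odd-length (linear-phase type I). The filter is applied forward
# and once more time-reversed, cancelling the group delay.
firZeroPhase <- function(x, b) {
  nb <- length(b)
  delay <- (nb - 1L) %/% 2L
  pad <- min(3L * delay, length(x) - 1L)
  xp <- c(2 * x[1] - rev(x[seq_len(pad) + 1L]), x,
          2 * x[length(x)] - rev(x[length(x) - seq_len(pad)]))
  onePass <- function(v) {
    y <- signal::fftfilt(b, c(v, numeric(nb)))
    y[seq_along(v) + delay]
  }
  y <- rev(onePass(rev(onePass(xp))))
  y[pad + seq_along(x)]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
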