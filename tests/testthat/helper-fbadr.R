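# Shared fixture builders; everything is generated in code.

randomSPD <- function(K, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(K * K), K, K)
  crossprod(A) / K + diag(K) * 0.5
}

sineRecording <- function(freq, fs = 500, dur = 4, K = 3, amp = 1, pre_s = 0.5) {
  n <- round((dur + pre_s) * fs)
  t <- seq_len(n) / fs
  x <- matrix(rep(amp * sin(2 * pi * freq * t), K), K, byrow = TRUE)
  new("Recording", data = x, fs = fs, onsetIndex = as.integer(pre_s * fs + 1),
      subject = "S01", modality = "audio", emotion = "pleasure", trial = 1L,
      channels = sprintf("CH%02d", seq_len(K)))
}

flatEpochSet <- function(n, K = 4, T = 50, fs = 100, seed = 1) {
  set.seed(seed)
  arr <- array(rnorm(K * T * n), c(K, T, n))
  labels <- data.frame(subject = "S01",
                       modality = rep(c("audio", "visual"), length.out = n),
                       emotion = rep(c("pleasure", "unpleasure"), each = ceiling(n / 2))[seq_len(n)],
                       trial = seq_len(n), window = 1L,
                       stringsAsFactors = FALSE)
  new("EpochSet", epochs = arr, fs = fs, labels = labels,
      channels = sprintf("CH%02d", seq_len(K)))
}

# Taylor-series matrix exponential with scaling-and-squaring: an oracle
# independent of the eigendecomposition route used by the package.
expmTaylor <- function(A, terms = 30L) {
  s <- max(0L, ceiling(log2(max(1, norm(A, "F")))))
  As <- A / 2^s
  out <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(terms)) {
    term <- term %*% As / k
    out <- out + term
  }
  for (i in seq_len(s)) out <- out %*% out
  out
}

# tiny generator config for pipeline tests
tinyGenConfig <- function(...) {
  args <- list(...)
  do.call(generatorConfig, utils::modifyList(
    list(n_subjects = 1L, n_trials = 3L, trial_s = 10, fs = 128,
         n_channels = 5L, class_sep = 1.5, shift_strength = 1,
         sensor_noise = 0.3, seed = 11L), args))
}

relFrob <- function(a, b) norm(a - b, "F") / norm(b, "F")

subsetEpochSetForTest <- function(es, idx) {
  new("EpochSet", epochs = es@epochs[, , idx, drop = FALSE], fs = es@fs,
      labels = es@labels[idx, , drop = FALSE], channels = es@channels)
}
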