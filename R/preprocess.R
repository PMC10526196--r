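# Preprocessing: broadband FIR bandpass, mains notch, baseline correction,
# non-overlapping windowed epoching, reference-channel removal.

#' Broadband zero-phase FIR bandpass
#'
#' Windowed-sinc (Hamming) FIR bandpass applied forward and backward
#' (zero phase). The filter order is chosen from the lower transition width
#' (one octave below \code{low}, i.e. about 3.3 fs / low taps), giving a
#' steep enough skirt to keep the 1 Hz edge while attenuating out-of-band
#' components by well over 40 dB after the two passes.
#'
#' @param recording a \linkS4class{Recording}.
#' @param low,high passband edges in Hz (defaults 1 and 50).
#' @return the filtered \linkS4class{Recording} (same length).
#' @export
bandpassBroadband <- function(recording, low = 1, high = 50) {
  fs <- recording@fs
  if (high >= fs / 2) stop("high edge must be below the Nyquist frequency")
  ntaps <- ceiling(3.3 * fs / low)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1L
  b <- signal::fir1(ntaps - 1L, c(low, high) / (fs / 2), type = "pass")
  out <- t(apply(recording@data, 1L, firZeroPhase, b = b))
  initialize(recording, data = out)
}

#' Mains notch filter
#'
#' Second-order IIR notch (biquad, Q = 30) at the mains frequency, applied
#' forward-backward for zero phase.
#'
#' @param recording a \linkS4class{Recording}.
#' @param freq notch frequency in Hz (default 50).
#' @param Q quality factor; bandwidth is freq/Q.
#' @return the filtered \linkS4class{Recording}.
#' @export
notchMains <- function(recording, freq = 50, Q = 30) {
  fs <- recording@fs
  if (freq >= fs / 2) stop("notch frequency must be below Nyquist")
  w0 <- 2 * pi * freq / fs
  alpha <- sin(w0) / (2 * Q)
  b <- c(1, -2 * cos(w0), 1) / (1 + alpha)
  a <- c(1, -2 * cos(w0) / (1 + alpha), (1 - alpha) / (1 + alpha))
  out <- t(apply(recording@data, 1L, function(ch)
    signal::filtfilt(signal::Arma(b = b, a = a), ch)))
  initialize(recording, data = out)
}

#' Baseline correction
#'
#' Subtracts, per channel, the mean over the \code{baseline_ms} interval
#' immediately preceding stimulus onset from the entire trial.
#'
#' @param recording a \linkS4class{Recording}.
#' @param baseline_ms baseline length in milliseconds (default 1000).
#' @return the corrected \linkS4class{Recording}.
#' @export
baselineCorrect <- function(recording, baseline_ms = 1000) {
  nBase <- round(baseline_ms * recording@fs / 1000)
  if (recording@onsetIndex - 1L < nBase)
    stop("insufficient pre-stimulus samples for the requested baseline")
  idx <- (recording@onsetIndex - nBase):(recording@onsetIndex - 1L)
  mu <- rowMeans(recording@data[, idx, drop = FALSE])
  initialize(recording, data = recording@data - mu)
}

#' Cut a recording into non-overlapping windows
#'
#' Epochs the stimulation period \code{span_s} (seconds relative to onset)
#' into consecutive non-overlapping windows of \code{window_s} seconds,
#' propagating the trial labels and numbering the windows.
#'
#' @param recording a \linkS4class{Recording} (or list of them).
#' @param window_s window length in seconds (default 5).
#' @param span_s length-2 span in seconds relative to stimulus onset
#'   (default c(0, 30)).
#' @return an \linkS4class{EpochSet}.
#' @export
epochWindows <- function(recording, window_s = 5, span_s = c(0, 30)) {
  if (is.list(recording)) {
    sets <- lapply(recording, epochWindows, window_s = window_s, span_s = span_s)
    return(bindEpochSets(sets))
  }
  span <- diff(span_s)
  nWin <- span / window_s
  if (abs(nWin - round(nWin)) > 1e-9)
    stop("span must be divisible by the window length")
  nWin <- as.integer(round(nWin))
  fs <- recording@fs
  wlen <- as.integer(round(window_s * fs))
  start0 <- recording@onsetIndex + round(span_s[1] * fs)
  if (start0 + nWin * wlen - 1L > ncol(recording@data))
    stop("recording too short for the requested span")
  K <- nrow(recording@data)
  arr <- array(0, c(K, wlen, nWin))
  for (w in seq_len(nWin)) {
    idx <- start0 + (w - 1L) * wlen + 0:(wlen - 1L)
    arr[, , w] <- recording@data[, idx]
  }
  labels <- data.frame(subject = recording@subject, modality = recording@modality,
                       emotion = recording@emotion, trial = recording@trial,
                       window = seq_len(nWin), stringsAsFactors = FALSE)
  new("EpochSet", epochs = arr, fs = fs, labels = labels,
      channels = recording@channels)
}

#' Concatenate epoch sets
#' @param sets list of \linkS4class{EpochSet}s with identical channels/fs.
#' @return a single \linkS4class{EpochSet}.
#' @export
bindEpochSets <- function(sets) {
  stopifnot(length(sets) >= 1)
  d <- dim(sets[[1]]@epochs)
  ns <- vapply(sets, nEpochs, numeric(1))
  arr <- array(0, c(d[1], d[2], sum(ns)))
  at <- 0L
  for (s in sets) {
    arr[, , at + seq_len(nEpochs(s))] <- s@epochs
    at <- at + nEpochs(s)
  }
  new("EpochSet", epochs = arr, fs = sets[[1]]@fs,
      labels = do.call(rbind, lapply(sets, epochLabels)),
      channels = sets[[1]]@channels)
}

#' Drop the reference channel
#'
#' Removes the named reference channel (default "FCz") from an epoch set; a
#' no-op with a warning when the montage has no such channel (as with the
#' synthetic montage). Applying it twice is idempotent.
#'
#' @param epochset an \linkS4class{EpochSet}.
#' @param channel reference channel name.
#' @return the reduced \linkS4class{EpochSet}.
#' @export
dropReference <- function(epochset, channel = "FCz") {
  pos <- match(channel, epochset@channels)
  if (is.na(pos)) {
    warning(sprintf("channel '%s' not present; epoch set unchanged", channel))
    return(epochset)
  }
  new("EpochSet", epochs = epochset@epochs[-pos, , , drop = FALSE],
      fs = epochset@fs, labels = epochset@labels,
      channels = epochset@channels[-pos])
}

#' Full per-recording preprocessing chain
#'
#' Broadband bandpass, mains notch, baseline correction, then windowed
#' epoching — the standard chain applied before feature extraction.
#'
#' @param recording a \linkS4class{Recording}.
#' @param low,high broadband edges, Hz.
#' @param notch mains frequency (NULL to skip).
#' @param baseline_ms baseline interval, ms.
#' @param window_s,span_s epoching parameters (span defaults to the full
#'   stimulation period).
#' @return an \linkS4class{EpochSet}.
#' @export
preprocessRecording <- function(recording, low = 1, high = 50, notch = 50,
                                baseline_ms = 1000, window_s = 5,
                                span_s = NULL) {
  if (is.null(span_s)) {
    stim_s <- (ncol(recording@data) - recording@onsetIndex + 1L) / recording@fs
    span_s <- c(0, floor(stim_s / window_s) * window_s)
  }
  r <- bandpassBroadband(recording, low, high)
  if (!is.null(notch)) r <- notchMains(r, notch)
  r <- baselineCorrect(r, baseline_ms)
  epochWindows(r, window_s, span_s)
}
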