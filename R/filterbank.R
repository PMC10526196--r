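# Six-band IIR filter bank.

#' Canonical six-band table
#'
#' Delta 1-4, Theta 4-8, Alpha 8-13, Beta1 13-20, Beta2 20-30 and Gamma
#' 30-50 Hz — the beta range split in two so that attention/emotion-related
#' low-beta and motor-related high-beta activity are separated.
#'
#' @return data.frame with columns index, name, low, high.
#' @export
bandDefinitions <- function() {
  data.frame(index = 1:6,
             name = c("Delta", "Theta", "Alpha", "Beta1", "Beta2", "Gamma"),
             low = c(1, 4, 8, 13, 20, 30),
             high = c(4, 8, 13, 20, 30, 50),
             stringsAsFactors = FALSE)
}

#' Split epochs into the six sub-bands
#'
#' Applies a 4th-order Butterworth bandpass per band, forward-backward
#' (zero phase), to every channel of every epoch. Band outputs share the
#' input's label table bit-exactly.
#'
#' @param epochset an \linkS4class{EpochSet}; sampling rate must exceed
#'   100 Hz so the 50 Hz band edge is below Nyquist.
#' @param bands band table (defaults to \code{\link{bandDefinitions}}).
#' @param order Butterworth order per band.
#' @return a \linkS4class{BandedEpochs}.
#' @export
applyFilterBank <- function(epochset, bands = bandDefinitions(), order = 4L) {
  fs <- epochset@fs
  if (fs <= 100) stop("sampling rate must exceed 100 Hz for the 50 Hz edge")
  d <- dim(epochset@epochs)
  out <- vector("list", nrow(bands))
  names(out) <- bands$name
  flat <- matrix(aperm(epochset@epochs, c(2, 1, 3)), nrow = d[2])  # T x (K*n)
  for (b in seq_len(nrow(bands))) {
    flt <- signal::butter(order, c(bands$low[b], bands$high[b]) / (fs / 2),
                          type = "pass")
    fb <- apply(flat, 2L, function(ch) signal::filtfilt(flt, ch))
    out[[b]] <- aperm(array(fb, c(d[2], d[1], d[3])), c(2, 1, 3))
  }
  new("BandedEpochs", bands = out, bandTable = bands, fs = fs,
      labels = epochset@labels, channels = epochset@channels)
}

#' Treat a broadband epoch set as a one-band bank
#'
#' Wraps an \linkS4class{EpochSet} as a single-"band" \linkS4class{BandedEpochs}
#' (used by the ablation variants that skip the filter bank).
#'
#' @param epochset an \linkS4class{EpochSet}.
#' @param low,high nominal band edges recorded in the band table.
#' @return a \linkS4class{BandedEpochs} with one band named "broadband".
#' @export
asBroadbandBank <- function(epochset, low = 1, high = 50) {
  new("BandedEpochs",
      bands = list(broadband = epochset@epochs),
      bandTable = data.frame(index = 1L, name = "broadband",
                             low = low, high = high, stringsAsFactors = FALSE),
      fs = epochset@fs, labels = epochset@labels, channels = epochset@channels)
}
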