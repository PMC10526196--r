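# Epoch container, EDF edge reader/writer and declarative run configuration.

#' Read / write the epoch container
#'
#' The pipeline's on-disk container: a named list with any of the elements
#' \code{raw} (list of \linkS4class{Recording}s), \code{epochs}
#' (\linkS4class{EpochSet}), \code{banded} (\linkS4class{BandedEpochs}),
#' \code{features} / \code{adapted} (\linkS4class{BandFeatures}),
#' \code{models} and \code{meta} (configs, seeds, package version),
#' serialized as RDS. Unknown elements are rejected so stale artifacts are
#' caught early.
#'
#' @param container named list of pipeline artifacts.
#' @param path file path.
#' @return \code{readEpochContainer}: the container list.
#' @export
writeEpochContainer <- function(container, path) {
  known <- c("raw", "epochs", "banded", "features", "adapted", "models", "meta")
  bad <- setdiff(names(container), known)
  if (length(bad)) stop("unknown container element(s): ", paste(bad, collapse = ", "))
  container$meta <- c(container$meta,
                      list(written = as.character(Sys.time()),
                           package_version = as.character(utils::packageVersion("fbadr"))))
  saveRDS(container, path)
  invisible(path)
}

#' @rdname writeEpochContainer
#' @param require optional element name that must be present (clear error
#'   naming the absent stage otherwise).
#' @export
readEpochContainer <- function(path, require = NULL) {
  if (!file.exists(path)) stop("container not found: ", path)
  x <- readRDS(path)
  if (!is.null(require) && is.null(x[[require]]))
    stop("container '", path, "' lacks the '", require,
         "' stage; run the upstream command first")
  x
}

padTo <- function(s, n) {
  s <- substr(paste0(s, strrep(" ", n)), 1, n)
  s
}

#' Write a recording to EDF
#'
#' Minimal European Data Format writer (16-bit, one 1 s data record per
#' second). Amplitudes are quantized to the channel's physical range; the
#' recording-identification header field carries the trial labels so
#' \code{\link{readEDF}} can restore them.
#'
#' @param recording a \linkS4class{Recording}; its length must be a whole
#'   number of seconds.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeEDF <- function(recording, path) {
  x <- recording@data
  fs <- recording@fs
  K <- nrow(x)
  nRec <- ncol(x) / fs
  if (abs(nRec - round(nRec)) > 1e-9)
    stop("recording length must be a whole number of 1 s records")
  nRec <- as.integer(round(nRec))
  physMin <- apply(x, 1, min); physMax <- apply(x, 1, max)
  physMax[physMax <= physMin] <- physMin[physMax <= physMin] + 1
  digMin <- -32768; digMax <- 32767
  con <- file(path, "wb")
  on.exit(close(con))
  lab <- sprintf("%s %s %s %d %d", recording@subject, recording@modality,
                 recording@emotion, recording@trial, recording@onsetIndex)
  hdr <- paste0(padTo("0", 8), padTo("X X X X", 80), padTo(lab, 80),
                padTo("01.01.24", 8), padTo("00.00.00", 8),
                padTo(as.character(256 * (K + 1)), 8), padTo("", 44),
                padTo(as.character(nRec), 8), padTo("1", 8),
                padTo(as.character(K), 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, w) writeChar(paste0(vapply(vals, padTo, "", n = w),
                                              collapse = ""), con, eos = NULL)
  field(recording@channels, 16)
  field(rep("", K), 80)
  field(rep("uV", K), 8)
  field(sprintf("%.8g", physMin)[seq_len(K)], 8)
  field(sprintf("%.8g", physMax)[seq_len(K)], 8)
  field(rep(as.character(digMin), K), 8)
  field(rep(as.character(digMax), K), 8)
  field(rep("", K), 80)
  field(rep(as.character(fs), K), 8)
  field(rep("", K), 32)
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRec)) {
    idx <- (r - 1) * fs + seq_len(fs)
    for (k in seq_len(K)) {
      dig <- round((x[k, idx] - physMin[k]) / scale[k] + digMin)
      writeBin(as.integer(pmin(pmax(dig, digMin), digMax)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file
#'
#' Minimal EDF reader (16-bit continuous signals, equal sampling rate across
#' channels). Labels are taken from \code{labels} when supplied, otherwise
#' parsed from the recording-identification field as written by
#' \code{\link{writeEDF}}; unparseable labels produce a warning and
#' "unknown" placeholders.
#'
#' @param path EDF file.
#' @param labels optional list(subject, modality, emotion, trial,
#'   onsetIndex) overriding the embedded labels.
#' @return a \linkS4class{Recording}.
#' @export
readEDF <- function(path, labels = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)
  rd(80)
  recId <- trimws(rd(80))
  rd(8); rd(8); rd(8); rd(44)
  nRec <- as.integer(rd(8))
  recDur <- as.numeric(rd(8))
  K <- as.integer(trimws(rd(4)))
  if (is.na(K) || K < 2) stop("EDF file must contain at least 2 channels: ", path)
  chn <- trimws(vapply(seq_len(K), function(i) rd(16), ""))
  for (w in c(80, 8)) for (i in seq_len(K)) rd(w)
  physMin <- as.numeric(vapply(seq_len(K), function(i) rd(8), ""))
  physMax <- as.numeric(vapply(seq_len(K), function(i) rd(8), ""))
  digMin <- as.numeric(vapply(seq_len(K), function(i) rd(8), ""))
  digMax <- as.numeric(vapply(seq_len(K), function(i) rd(8), ""))
  for (i in seq_len(K)) rd(80)
  spr <- as.integer(vapply(seq_len(K), function(i) rd(8), ""))
  for (i in seq_len(K)) rd(32)
  if (length(unique(spr)) != 1)
    stop("channels with differing sampling rates are not supported: ", path)
  fs <- spr[1] / recDur
  x <- matrix(0, K, nRec * spr[1])
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRec)) {
    idx <- (r - 1) * spr[1] + seq_len(spr[1])
    for (k in seq_len(K)) {
      dig <- readBin(con, "integer", spr[1], size = 2, signed = TRUE,
                     endian = "little")
      x[k, idx] <- (dig - digMin[k]) * scale[k] + physMin[k]
    }
  }
  if (is.null(labels)) {
    parts <- strsplit(recId, " +")[[1]]
    if (length(parts) >= 5 && parts[2] %in% .MODALITIES &&
        parts[3] %in% .EMOTIONS) {
      labels <- list(subject = parts[1], modality = parts[2],
                     emotion = parts[3], trial = as.integer(parts[4]),
                     onsetIndex = as.integer(parts[5]))
    } else {
      warning("no label mapping supplied and none embedded; using 'unknown'")
      labels <- list(subject = "unknown", modality = "unknown",
                     emotion = "unknown", trial = 1L, onsetIndex = 1L)
    }
  }
  new("Recording", data = x, fs = fs,
      onsetIndex = as.integer(labels$onsetIndex %||% 1L),
      subject = labels$subject, modality = labels$modality,
      emotion = labels$emotion, trial = as.integer(labels$trial %||% 1L),
      channels = chn)
}

#' Read a declarative run configuration
#'
#' YAML file with optional sections \code{generator}, \code{preprocess},
#' \code{adapt}, \code{classify}, \code{protocol} and a global \code{seed};
#' unknown sections or keys are rejected. Values override the printed
#' defaults of the corresponding constructors.
#'
#' @param path YAML file.
#' @return list with instantiated configs.
#' @export
readRunConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("generator", "preprocess", "adapt", "classify", "protocol", "seed")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  seed <- as.integer(y$seed %||% 1L)
  gen <- do.call(generatorConfig, c(y$generator %||% list()))
  acfg <- do.call(adaptTrainConfig, c(y$adapt %||% list()))
  prot <- do.call(protocolConfig,
                  c(y$protocol %||% list(), list(adapt_config = acfg)))
  list(generator = gen, preprocess = y$preprocess %||% list(),
       classify = y$classify %||% list(), protocol = prot, seed = seed)
}
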