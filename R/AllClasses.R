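#' @import methods
NULL

.MODALITIES <- c("audio", "visual", "audiovisual")
.EMOTIONS <- c("pleasure", "unpleasure")

#' Single-trial multichannel recording
#'
#' A continuous multichannel EEG-like trial: a channels-by-time amplitude
#' matrix with its sampling rate, the sample index of stimulus onset
#' (separating the pre-stimulus baseline from the stimulation period) and the
#' trial's labels (subject, sensory modality, emotion, trial number).
#'
#' @slot data numeric matrix, channels x time-points.
#' @slot fs sampling rate in Hz.
#' @slot onsetIndex integer; first sample of the stimulation period
#'   (samples 1..onsetIndex-1 are pre-stimulus baseline).
#' @slot subject,modality,emotion,trial trial labels.
#' @slot channels channel names, one per row of \code{data}.
#' @exportClass Recording
setClass("Recording", representation(
  data = "matrix", fs = "numeric", onsetIndex = "integer",
  subject = "character", modality = "character", emotion = "character",
  trial = "integer", channels = "character"
))

setValidity("Recording", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (any(!is.finite(object@data))) msg <- c(msg, "data contains NaN/Inf")
  if (length(object@fs) != 1 || object@fs <= 0) msg <- c(msg, "fs must be a positive scalar")
  if (object@onsetIndex < 1 || object@onsetIndex > ncol(object@data) + 1)
    msg <- c(msg, "onsetIndex out of range")
  if (length(object@channels) != nrow(object@data))
    msg <- c(msg, "channels must name every row of data")
  if (!object@modality %in% c(.MODALITIES, "unknown"))
    msg <- c(msg, "unrecognized modality")
  if (!object@emotion %in% c(.EMOTIONS, "unknown"))
    msg <- c(msg, "unrecognized emotion")
  if (length(msg)) msg else TRUE
})

#' Labeled windowed epochs
#'
#' Fixed-length windows cut from recordings, stored as a channels x time x
#' epoch array with an aligned label table (one row per epoch: subject,
#' modality, emotion, trial, window).
#'
#' @slot epochs numeric array, K x T x n.
#' @slot fs sampling rate in Hz.
#' @slot labels data.frame with columns subject, modality, emotion, trial,
#'   window; \code{nrow(labels) == dim(epochs)[3]}.
#' @slot channels channel names.
#' @exportClass EpochSet
setClass("EpochSet", representation(
  epochs = "array", fs = "numeric", labels = "data.frame",
  channels = "character"
))

setValidity("EpochSet", function(object) {
  msg <- character()
  d <- dim(object@epochs)
  if (length(d) != 3) msg <- c(msg, "epochs must be a 3-d array (K x T x n)")
  if (any(!is.finite(object@epochs))) msg <- c(msg, "epochs contain NaN/Inf")
  need <- c("subject", "modality", "emotion", "trial", "window")
  if (!all(need %in% names(object@labels)))
    msg <- c(msg, paste("labels must have columns:", paste(need, collapse = ", ")))
  if (length(d) == 3 && nrow(object@labels) != d[3])
    msg <- c(msg, "label table not aligned with epochs")
  if (length(d) == 3 && length(object@channels) != d[1])
    msg <- c(msg, "channels must name every epoch row")
  if (length(msg)) msg else TRUE
})

#' Per-band filtered epochs
#'
#' One \linkS4class{EpochSet} per sub-band of the filter bank, sharing a
#' single label table (label order is identical across bands).
#'
#' @slot bands named list of K x T x n arrays, one per band.
#' @slot bandTable data.frame of band definitions (index, name, low, high).
#' @slot fs sampling rate in Hz.
#' @slot labels shared epoch label table.
#' @slot channels channel names.
#' @exportClass BandedEpochs
setClass("BandedEpochs", representation(
  bands = "list", bandTable = "data.frame", fs = "numeric",
  labels = "data.frame", channels = "character"
))

setValidity("BandedEpochs", function(object) {
  msg <- character()
  if (length(object@bands) != nrow(object@bandTable))
    msg <- c(msg, "one array per band definition required")
  n <- vapply(object@bands, function(b) dim(b)[3], numeric(1))
  if (length(n) && any(n != nrow(object@labels)))
    msg <- c(msg, "epoch counts differ across bands or from the label table")
  if (length(msg)) msg else TRUE
})

#' Per-band tangent-space feature matrices
#'
#' Flattened Riemannian tangent-space features: for each band an n x K^2
#' matrix (row-major flattening of the symmetric tangent matrices), plus the
#' shared label table and the per-band SPD reference points used for the
#' projection.
#'
#' @slot features named list of n x F matrices (F = K^2).
#' @slot references named list of K x K SPD reference matrices.
#' @slot labels epoch label table aligned with the feature rows.
#' @exportClass BandFeatures
setClass("BandFeatures", representation(
  features = "list", references = "list", labels = "data.frame"
))

setValidity("BandFeatures", function(object) {
  msg <- character()
  if (!identical(names(object@features), names(object@references)))
    msg <- c(msg, "feature and reference band names must agree")
  n <- vapply(object@features, nrow, numeric(1))
  if (length(n) && any(n != nrow(object@labels)))
    msg <- c(msg, "feature rows not aligned with label table")
  if (length(msg)) msg else TRUE
})

#' Trained adversarial domain-adaptation model
#'
#' A conditional Wasserstein adaptor/critic pair (or one pair per emotion
#' class under class-partitioned conditioning) for one band, together with
#' the feature scaler fitted on target-domain training data and the per-epoch
#' training loss history.
#'
#' @slot adaptors named list (by class, or "all") of adaptor parameter lists.
#' @slot critics matching critic parameter lists.
#' @slot adaptorSpec,criticSpec network layer plans.
#' @slot scaler feature scaler (see \code{\link{fitFeatureScaler}}).
#' @slot conditioning "partition" or "onehot".
#' @slot classes class alphabet (sorted).
#' @slot history data.frame of per-epoch adaptor and critic losses.
#' @exportClass AdapterModel
setClass("AdapterModel", representation(
  adaptors = "list", critics = "list", adaptorSpec = "list",
  criticSpec = "list", scaler = "list", conditioning = "character",
  classes = "character", history = "data.frame"
))

#' Stacked per-band SVM ensemble
#'
#' One polynomial-kernel SVM per band plus a logistic-regression
#' meta-classifier fitted on the validation-set band predictions.
#'
#' @slot svms named list of fitted \code{e1071::svm} objects (one per band).
#' @slot meta fitted logistic regression (\code{glm}) or NULL-like empty list
#'   for single-band variants.
#' @slot classes class alphabet, sorted lexicographically; the first class is
#'   the positive ("pleasure") class.
#' @exportClass EnsembleModel
setClass("EnsembleModel", representation(
  svms = "list", meta = "ANY", classes = "character"
))

setValidity("EnsembleModel", function(object) {
  if (length(object@classes) != 2) return("exactly two classes supported")
  TRUE
})

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz\n",
              nrow(object@data), ncol(object@data), object@fs))
  cat(sprintf("  subject=%s modality=%s emotion=%s trial=%d onset=%d\n",
              object@subject, object@modality, object@emotion,
              object@trial, object@onsetIndex))
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochSet: %d epochs of %d channels x %d samples @ %g Hz\n",
              d[3], d[1], d[2], object@fs))
  cat(sprintf("  subjects: %s | modalities: %s | emotions: %s\n",
              paste(unique(object@labels$subject), collapse = ","),
              paste(unique(object@labels$modality), collapse = ","),
              paste(unique(object@labels$emotion), collapse = ",")))
})

setMethod("show", "BandedEpochs", function(object) {
  cat(sprintf("BandedEpochs: %d bands x %d epochs (%d channels) @ %g Hz\n",
              length(object@bands), nrow(object@labels),
              length(object@channels), object@fs))
  print(object@bandTable, row.names = FALSE)
})

setMethod("show", "BandFeatures", function(object) {
  f <- object@features
  cat(sprintf("BandFeatures: %d bands, %d epochs, feature dim %d\n",
              length(f), if (length(f)) nrow(f[[1]]) else 0L,
              if (length(f)) ncol(f[[1]]) else 0L))
})

setMethod("show", "AdapterModel", function(object) {
  cat(sprintf("AdapterModel: %s conditioning, classes: %s, %d training epochs\n",
              object@conditioning, paste(object@classes, collapse = "/"),
              nrow(object@history)))
})

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel: %d band SVM(s)%s, classes: %s\n",
              length(object@svms),
              if (length(object@meta)) " + LR meta-classifier" else "",
              paste(object@classes, collapse = "/")))
})
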