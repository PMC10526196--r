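# Accessor generics: slot access stays behind these.

#' @export
setGeneric("epochData", function(x, ...) standardGeneric("epochData"))
#' @export
setGeneric("epochLabels", function(x) standardGeneric("epochLabels"))
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @export
setGeneric("bandNames", function(x) standardGeneric("bandNames"))
#' @export
setGeneric("bandFeatureMatrix", function(x, band) standardGeneric("bandFeatureMatrix"))
#' @export
setGeneric("referenceMatrix", function(x, band) standardGeneric("referenceMatrix"))
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))

#' Epoch array accessor
#' @param x an EpochSet or BandedEpochs.
#' @param band band name or index (BandedEpochs only).
#' @param ... unused.
#' @return K x T x n numeric array.
#' @export
setMethod("epochData", "EpochSet", function(x, ...) x@epochs)

#' @rdname epochData
#' @export
setMethod("epochData", "BandedEpochs", function(x, band = 1L, ...) x@bands[[band]])

#' @export
setMethod("epochLabels", "EpochSet", function(x) x@labels)
#' @export
setMethod("epochLabels", "BandedEpochs", function(x) x@labels)
#' @export
setMethod("epochLabels", "BandFeatures", function(x) x@labels)

#' @export
setMethod("nEpochs", "EpochSet", function(x) dim(x@epochs)[3])
#' @export
setMethod("nEpochs", "BandedEpochs", function(x) nrow(x@labels))
#' @export
setMethod("nEpochs", "BandFeatures", function(x) nrow(x@labels))

#' @export
setMethod("samplingRate", "Recording", function(x) x@fs)
#' @export
setMethod("samplingRate", "EpochSet", function(x) x@fs)
#' @export
setMethod("samplingRate", "BandedEpochs", function(x) x@fs)

#' @export
setMethod("channelNames", "Recording", function(x) x@channels)
#' @export
setMethod("channelNames", "EpochSet", function(x) x@channels)
#' @export
setMethod("channelNames", "BandedEpochs", function(x) x@channels)

#' @export
setMethod("bandNames", "BandedEpochs", function(x) names(x@bands))
#' @export
setMethod("bandNames", "BandFeatures", function(x) names(x@features))

#' Per-band feature and reference accessors
#' @param x a BandFeatures object.
#' @param band band name or index.
#' @return \code{bandFeatureMatrix}: n x F feature matrix;
#'   \code{referenceMatrix}: the K x K SPD reference point of that band.
#' @export
setMethod("bandFeatureMatrix", "BandFeatures", function(x, band) x@features[[band]])

#' @rdname bandFeatureMatrix
#' @export
setMethod("referenceMatrix", "BandFeatures", function(x, band) x@references[[band]])

#' @export
setMethod("lossHistory", "AdapterModel", function(x) x@history)
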