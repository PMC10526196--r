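# Stacked per-band SVM ensemble with a logistic-regression meta-classifier.
#
# One polynomial-kernel SVM per band (C = 0.001, gamma = 10, cubic kernel,
# the published final hyperparameters) trained on target-train + adapted
# source features; band label predictions on the validation split feed a
# logistic regression blender. Classes are ordered lexicographically
# ("pleasure" < "unpleasure"); band predictions enter the meta-learner as
# {0,1} with 1 = the positive ("pleasure") class.

svmKernelName <- function(kernel) {
  switch(kernel, poly = "polynomial", polynomial = "polynomial",
         linear = "linear", rbf = "radial",
         stop("unknown kernel: ", kernel))
}

#' Train the per-band SVMs
#'
#' @param feature_list named list (band -> n x F training feature matrix).
#' @param labels emotion labels, length n (same for every band).
#' @param cost,gamma,kernel,degree SVM hyperparameters; defaults are the
#'   published values (C = 0.001, polynomial kernel, gamma = 10).
#' @return named list of fitted \code{e1071::svm} objects.
#' @export
trainBandSvms <- function(feature_list, labels, cost = 0.001, gamma = 10,
                          kernel = "poly", degree = 3) {
  classes <- sort(unique(as.character(labels)))
  if (length(classes) < 2) stop("training labels contain a single class")
  y <- factor(as.character(labels), levels = classes)
  lapply(feature_list, function(x)
    e1071::svm(x, y, kernel = svmKernelName(kernel), cost = cost,
               gamma = gamma, degree = degree, coef0 = 0, scale = FALSE))
}

# n x n_bands {0,1} prediction matrix (1 = positive class) for a feature set
bandPredictionMatrix <- function(svms, feature_list, classes) {
  pos <- classes[1]
  out <- sapply(names(svms), function(b)
    as.integer(predict(svms[[b]], feature_list[[b]]) == pos))
  matrix(out, ncol = length(svms),
         dimnames = list(NULL, names(svms)))
}

#' Train the logistic-regression meta-classifier
#'
#' Blending: the meta-learner is fitted on the band-wise validation-set
#' label predictions (encoded \{0,1\}) against the true validation labels,
#' with default glm settings.
#'
#' @param band_predictions n_v x n_bands \{0,1\} matrix of validation
#'   predictions.
#' @param truth true validation labels (both classes present, n_v >= 2).
#' @return fitted \code{glm} object.
#' @export
trainMeta <- function(band_predictions, truth) {
  classes <- sort(unique(as.character(truth)))
  if (length(classes) < 2) stop("validation labels contain a single class")
  if (length(truth) < 2) stop("validation set too small")
  df <- as.data.frame(band_predictions)
  names(df) <- paste0("band", seq_len(ncol(band_predictions)))
  df$.y <- as.integer(as.character(truth) == classes[1])
  suppressWarnings(stats::glm(.y ~ ., family = stats::binomial(), data = df))
}

metaPredict <- function(meta, band_predictions, classes) {
  df <- as.data.frame(band_predictions)
  names(df) <- paste0("band", seq_len(ncol(band_predictions)))
  p <- suppressWarnings(stats::predict(meta, newdata = df, type = "response"))
  ifelse(p > 0.5, classes[1], classes[2])
}

#' Fit the full ensemble
#'
#' Trains the per-band SVMs on the training features and, when more than one
#' band is present, the LR meta-classifier on the validation-set band
#' predictions. With a single band (no filter bank) the lone SVM predicts
#' directly and no meta-learner is fitted.
#'
#' @param train_features named list (band -> training feature matrix).
#' @param train_labels training labels.
#' @param val_features matching per-band validation features (ignored for
#'   single-band models).
#' @param val_labels validation labels.
#' @param ... SVM hyperparameters passed to \code{\link{trainBandSvms}}.
#' @return an \linkS4class{EnsembleModel}.
#' @export
trainEnsemble <- function(train_features, train_labels,
                          val_features = NULL, val_labels = NULL, ...) {
  classes <- sort(unique(as.character(train_labels)))
  svms <- trainBandSvms(train_features, train_labels, ...)
  meta <- list()
  if (length(svms) > 1) {
    stopifnot(!is.null(val_features), !is.null(val_labels))
    vp <- bandPredictionMatrix(svms, val_features, classes)
    meta <- trainMeta(vp, val_labels)
  }
  new("EnsembleModel", svms = svms, meta = meta, classes = classes)
}

#' Predict emotions with the ensemble
#'
#' Per-band SVM predictions followed by the meta-classifier (or the single
#' SVM directly for single-band models). Deterministic.
#'
#' @param model an \linkS4class{EnsembleModel}.
#' @param feature_list named per-band test feature matrices covering every
#'   band of the model.
#' @return character vector of predicted labels.
#' @export
predictEnsemble <- function(model, feature_list) {
  missing <- setdiff(names(model@svms), names(feature_list))
  if (length(missing))
    stop("missing band feature(s): ", paste(missing, collapse = ", "))
  bp <- bandPredictionMatrix(model@svms, feature_list, model@classes)
  if (length(model@svms) == 1)
    return(ifelse(bp[, 1] == 1, model@classes[1], model@classes[2]))
  metaPredict(model@meta, bp, model@classes)
}

#' Classification accuracy
#'
#' (TP + TN) / (TP + FN + TN + FP) with pleasure the positive class —
#' equivalently the fraction of correct predictions.
#'
#' @param predictions,truths aligned nonempty label vectors.
#' @return accuracy in [0, 1].
#' @export
classificationAccuracy <- function(predictions, truths) {
  if (length(predictions) == 0 || length(predictions) != length(truths))
    stop("predictions and truths must be nonempty and aligned")
  mean(as.character(predictions) == as.character(truths))
}

#' Confusion counts
#' @param predictions,truths aligned label vectors.
#' @param positive positive-class label (default "pleasure").
#' @return named vector TP, FN, TN, FP.
#' @export
confusionCounts <- function(predictions, truths, positive = "pleasure") {
  p <- as.character(predictions); t <- as.character(truths)
  c(TP = sum(p == positive & t == positive),
    FN = sum(p != positive & t == positive),
    TN = sum(p != positive & t != positive),
    FP = sum(p == positive & t != positive))
}
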