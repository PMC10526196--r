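# Conditional Wasserstein adversarial domain adaptation with gradient
# penalty. An adaptor maps source-modality tangent features to
# target-modality-like features; a critic estimates the Wasserstein
# discrepancy between target features and adapted source features,
# regularized by the unit-gradient-norm penalty on straight-line
# interpolates. Conditioning on the emotion label is realized by default as
# one adaptor/critic pair per class ("partition"), keeping the published
# layer shapes exact; a one-hot concatenation variant is available.

#' Adaptation training configuration
#'
#' Defaults follow the published training protocol: 100 epochs, batch 32,
#' Adam with learning rate 0.001. The penalty weight defaults to 10, the
#' convention of the gradient-penalty Wasserstein literature; one critic
#' update per adaptor update.
#'
#' @param epochs training epochs.
#' @param batch batch size.
#' @param lr Adam learning rate.
#' @param beta1,beta2 Adam moment decays; beta1 = 0.5 is the adversarial
#'   training convention (momentum-heavy updates destabilize the min-max
#'   game).
#' @param lambda_gp gradient-penalty weight.
#' @param critic_steps critic updates per adaptor update.
#' @param conditioning "partition" (per-class models) or "onehot"
#'   (label concatenated to network inputs).
#' @param seed RNG seed for initialization and batching.
#' @return config list.
#' @export
adaptTrainConfig <- function(epochs = 100L, batch = 32L, lr = 0.001,
                             beta1 = 0.5, beta2 = 0.999,
                             lambda_gp = 10, critic_steps = 1L,
                             conditioning = c("partition", "onehot"),
                             seed = 1L) {
  conditioning <- match.arg(conditioning)
  stopifnot(epochs >= 1, batch >= 1, lr > 0, lambda_gp >= 0, critic_steps >= 1,
            beta1 >= 0, beta1 < 1, beta2 > 0, beta2 < 1)
  list(epochs = as.integer(epochs), batch = as.integer(batch), lr = lr,
       beta1 = beta1, beta2 = beta2,
       lambda_gp = lambda_gp, critic_steps = as.integer(critic_steps),
       conditioning = conditioning, seed = as.integer(seed))
}

#' Fit a per-dimension feature scaler
#'
#' Affine map of each feature dimension into [-1, 1], fitted on
#' target-domain training features only (the tanh-bounded adaptor output
#' lives there). Constant dimensions map to 0 with a unit inverse-slope
#' guard so the inverse is well defined.
#'
#' @param features n x F training feature matrix.
#' @return scaler list (center, halfrange).
#' @export
fitFeatureScaler <- function(features) {
  stopifnot(nrow(features) >= 1)
  lo <- apply(features, 2, min)
  hi <- apply(features, 2, max)
  half <- (hi - lo) / 2
  half[half == 0] <- 1
  list(center = (hi + lo) / 2, halfrange = half)
}

#' @rdname fitFeatureScaler
#' @param scaler a fitted scaler.
#' @export
applyScaler <- function(scaler, features) {
  sweep(sweep(features, 2, scaler$center), 2, scaler$halfrange, "/")
}

#' @rdname fitFeatureScaler
#' @export
invertScaler <- function(scaler, features) {
  sweep(sweep(features, 2, scaler$halfrange, "*"), 2, scaler$center, "+")
}

# one-hot label encoding, columns in sorted class order
oneHot <- function(labels, classes) {
  m <- matrix(0, length(labels), length(classes))
  m[cbind(seq_along(labels), match(labels, classes))] <- 1
  m
}

# gradient-penalty node: criticFn takes an adnode and returns n x 1 scores
gpNode <- function(criticFn, x_target, x_adapted, u) {
  xt <- adValue(x_target); xa <- adValue(x_adapted)
  stopifnot(all(dim(xt) == dim(xa)))
  xhatVal <- u * xt + (1 - u) * xa
  xhat <- adNode(xhatVal)
  D <- adSum(criticFn(xhat))
  g <- adGrad(D, list(xhat))[[1]]
  nrm <- adPowC(adAddC(adRowSums(adMul(g, g)), 1e-12), 0.5)
  dev <- adAddC(nrm, -1)
  adMean(adMul(dev, dev))
}

#' Wasserstein gradient penalty
#'
#' Mean over the batch of \eqn{(\lVert \nabla_{\hat x} D(\hat x) \rVert_2 - 1)^2}
#' where \eqn{\hat x = u x_{target} + (1-u) x_{adapted}} with
#' \eqn{u \sim U(0,1)} per sample — the soft Lipschitz constraint of the
#' Wasserstein critic.
#'
#' @param criticFn function mapping an input node (n x F) to critic scores
#'   (n x 1 node); typically a closure over \code{\link{criticForward}}.
#' @param x_target,x_adapted matching n x F batches.
#' @param u optional interpolation weights (drawn from the current RNG
#'   stream when NULL).
#' @return scalar penalty value.
#' @export
gradientPenalty <- function(criticFn, x_target, x_adapted, u = NULL) {
  if (is.null(u)) u <- stats::runif(nrow(x_target))
  adValue(gpNode(criticFn, x_target, x_adapted, u))[1, 1]
}

# Single adaptor/critic pair on scaled features (one conditioning cell).
# Under one-hot conditioning condT/condS carry the label encodings that are
# appended to the adaptor input and to every critic input; the adaptor still
# outputs bare features (ncol(x_target)).
trainPair <- function(x_target, x_source, aspec, cspec, config,
                      condT = NULL, condS = NULL) {
  F <- ncol(x_target)
  ap <- initAdaptor(aspec, out_dim = F)
  cp <- initCritic(cspec)
  astate <- adamInit(ap)
  cstate <- adamInit(cp)
  nT <- nrow(x_target); nS <- nrow(x_source)
  bs <- min(config$batch, nS)         # target batches resample if smaller
  nc <- if (is.null(condS)) 0L else ncol(condS)
  # append constant condition columns to a feature node
  concat <- function(node, cond) {
    if (is.null(cond)) return(node)
    adAdd(adUncols(node, seq_len(F), F + nc),
          adWrap(cbind(matrix(0, nrow(cond), F), cond)))
  }
  histC <- histA <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(nS)
    nBatch <- max(1L, floor(nS / bs))
    lc <- la <- 0
    for (bt in seq_len(nBatch)) {
      sIdx <- ord[(bt - 1L) * bs + seq_len(bs)]
      xs <- x_source[sIdx, , drop = FALSE]
      csS <- if (nc) condS[sIdx, , drop = FALSE] else NULL
      adIn <- if (nc) cbind(xs, csS) else xs
      for (cs in seq_len(config$critic_steps)) {
        tIdx <- sample.int(nT, bs, replace = nT < bs)
        xt <- x_target[tIdx, , drop = FALSE]
        csT <- if (nc) condT[tIdx, , drop = FALSE] else NULL
        xad <- adValue(adaptorForward(ap, adIn, aspec))    # detached
        pn <- lapply(cp, adNode)
        cf <- function(z) criticForward(pn, z, cspec)
        u <- stats::runif(bs)
        xtIn <- if (nc) cbind(xt, csT) else xt
        xadIn <- if (nc) cbind(xad, csS) else xad
        wass <- adSub(adMean(cf(xadIn)), adMean(cf(xtIn))) # -(E[D(xt)]-E[D(xad)])
        loss <- adAdd(wass,
                      adScale(gpNode(cf, xtIn, xadIn, u), config$lambda_gp))
        gs <- adGrad(loss, pn)
        names(gs) <- names(cp)
        upd <- adamStep(cp, lapply(gs, adValue), cstate, config$lr,
                        config$beta1, config$beta2)
        cp <- upd$params; cstate <- upd$state
        lc <- lc + adValue(loss)[1, 1]
      }
      # adaptor step: minimize -E[D(AD(r))]
      an <- lapply(ap, adNode)
      fake <- adaptorForward(an, adIn, aspec)
      aloss <- adScale(adMean(criticForward(cp, concat(fake, csS), cspec)), -1)
      gs <- adGrad(aloss, an)
      names(gs) <- names(ap)
      upd <- adamStep(ap, lapply(gs, adValue), astate, config$lr,
                      config$beta1, config$beta2)
      ap <- upd$params; astate <- upd$state
      la <- la + adValue(aloss)[1, 1]
    }
    histC[ep] <- lc / (nBatch * config$critic_steps)
    histA[ep] <- la / nBatch
  }
  list(adaptor = ap, critic = cp, histC = histC, histA = histA)
}

#' Train conditional adversarial domain adaptation
#'
#' Alternating Wasserstein-critic / adaptor updates on scaled tangent
#' features: the critic maximizes
#' \eqn{E[D(x_a|y)] - E[D(AD(r)|y)] - \lambda GP}, the adaptor minimizes
#' \eqn{-E[D(AD(r)|y)]}. Features are scaled into [-1,1] by a scaler fitted
#' on the target training features; under the default "partition"
#' conditioning one pair is trained per emotion class.
#'
#' @param target_features,target_labels target-domain training features
#'   (n_t x F) and their emotion labels.
#' @param source_features,source_labels source-domain features and labels.
#' @param aspec,cspec network plans (\code{\link{adaptorSpec}},
#'   \code{\link{criticSpec}}); their input dimension must equal F
#'   (F + number of classes under one-hot conditioning).
#' @param config an \code{\link{adaptTrainConfig}}.
#' @return an \linkS4class{AdapterModel} with per-epoch loss history.
#' @export
trainAdaptation <- function(target_features, target_labels,
                            source_features, source_labels,
                            aspec = NULL, cspec = NULL,
                            config = adaptTrainConfig()) {
  classes <- sort(unique(as.character(source_labels)))
  missing <- setdiff(classes, unique(as.character(target_labels)))
  if (length(missing))
    stop("class(es) present in source but absent in target: ",
         paste(missing, collapse = ", "))
  F <- ncol(target_features)
  nc <- length(classes)
  inDim <- if (config$conditioning == "onehot") F + nc else F
  if (is.null(aspec)) aspec <- adaptorSpec(input_dim = inDim)
  if (is.null(cspec)) cspec <- criticSpec(input_dim = inDim)
  stopifnot(aspec$input_dim == inDim, cspec$input_dim == inDim)
  scaler <- fitFeatureScaler(target_features)
  xt <- applyScaler(scaler, target_features)
  xs <- applyScaler(scaler, source_features)
  withSeed(config$seed, {
    if (config$conditioning == "partition") {
      fits <- lapply(classes, function(cl) {
        trainPair(xt[target_labels == cl, , drop = FALSE],
                  xs[source_labels == cl, , drop = FALSE],
                  aspec, cspec, config)
      })
      names(fits) <- classes
    } else {
      fits <- list(all = trainPair(
        xt, xs, aspec, cspec, config,
        condT = oneHot(as.character(target_labels), classes),
        condS = oneHot(as.character(source_labels), classes)))
    }
    nEp <- config$epochs
    hist <- data.frame(
      epoch = seq_len(nEp),
      critic_loss = rowMeans(matrix(sapply(fits, `[[`, "histC"), nrow = nEp)),
      adaptor_loss = rowMeans(matrix(sapply(fits, `[[`, "histA"), nrow = nEp)))
    new("AdapterModel",
        adaptors = lapply(fits, `[[`, "adaptor"),
        critics = lapply(fits, `[[`, "critic"),
        adaptorSpec = aspec, criticSpec = cspec, scaler = scaler,
        conditioning = config$conditioning, classes = classes,
        history = hist)
  })
}

#' Map source features through a trained adaptor
#'
#' Shape-preserving: n x F in, n x F out, each dimension in (-1, 1) (tanh).
#' Inputs are scaled with the model's stored target-fitted scaler unless
#' already scaled; outputs stay in the scaled feature space, where the
#' downstream classifiers operate.
#'
#' @param model a trained \linkS4class{AdapterModel}.
#' @param source_features n x F source-domain features.
#' @param labels emotion labels (length n) selecting the per-class adaptor.
#' @param scaled TRUE if \code{source_features} are already scaled.
#' @return n x F adapted feature matrix (scaled space).
#' @export
adaptFeatures <- function(model, source_features, labels, scaled = FALSE) {
  F0 <- length(model@scaler$center)
  if (ncol(source_features) != F0)
    stop("feature dimension mismatch: expected ", F0)
  x <- if (scaled) source_features else applyScaler(model@scaler, source_features)
  out <- matrix(0, nrow(x), ncol(x))
  labels <- as.character(labels)
  if (model@conditioning == "partition") {
    for (cl in model@classes) {
      sel <- labels == cl
      if (!any(sel)) next
      out[sel, ] <- adValue(adaptorForward(model@adaptors[[cl]],
                                           x[sel, , drop = FALSE],
                                           model@adaptorSpec))
    }
  } else {
    xh <- cbind(x, oneHot(labels, model@classes))
    out <- adValue(adaptorForward(model@adaptors$all, xh, model@adaptorSpec))
  }
  out
}

#' Linear-classifier separability of two feature samples
#'
#' Trains a linear SVM to tell sample a from sample b on a random half and
#' reports held-out accuracy — near 0.5 when the two distributions match,
#' near 1 when they are well separated. Used to quantify how much of the
#' modality domain shift the adapter removed.
#'
#' @param a,b feature matrices (rows = samples).
#' @param seed RNG seed for the split.
#' @return held-out domain-classification accuracy in [0, 1].
#' @export
domainSeparability <- function(a, b, seed = 1L) {
  x <- rbind(a, b)
  y <- factor(rep(c("a", "b"), c(nrow(a), nrow(b))))
  withSeed(seed, {
    tr <- unlist(lapply(split(seq_along(y), y), function(i)
      sample(i, floor(length(i) / 2))))
    fit <- e1071::svm(x[tr, , drop = FALSE], y[tr], kernel = "linear",
                      cost = 1, scale = FALSE)
    mean(predict(fit, x[-tr, , drop = FALSE]) == y[-tr])
  })
}
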