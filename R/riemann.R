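# Riemannian tangent-space features on SPD spatial covariance matrices.

#' Spatial covariance of one epoch
#'
#' \eqn{X X^T / (N - 1)} for a zero-mean (filtered) K x N epoch; the mean is
#' not re-subtracted because the preceding bandpass removes the DC component.
#'
#' @param epoch numeric K x N matrix (N >= 2).
#' @return K x K symmetric matrix.
#' @export
covarianceMatrix <- function(epoch) {
  if (ncol(epoch) < 2) stop("at least two time points required")
  C <- tcrossprod(epoch) / (ncol(epoch) - 1)
  (C + t(C)) / 2
}

#' Oracle-approximating shrinkage (OAS) regularization
#'
#' Convex combination \eqn{(1-\rho) C + \rho (tr(C)/K) I} with the
#' closed-form OAS intensity
#' \deqn{\rho = \min\!\left(1, \frac{(1 - 2/K)\,tr(C^2) + tr(C)^2}
#'   {(n + 1 - 2/K)\,(tr(C^2) - tr(C)^2/K)}\right),}
#' which blends the sample covariance toward a scaled identity and guarantees
#' positive definiteness whenever tr(C) > 0. The intensity vanishes as the
#' number of observations grows.
#'
#' @param cov symmetric K x K sample covariance.
#' @param n_obs number of observations (time points) behind \code{cov}.
#' @return list with elements \code{matrix} (SPD K x K) and \code{rho}.
#' @export
oasRegularize <- function(cov, n_obs) {
  K <- nrow(cov)
  tr <- sum(diag(cov))
  if (tr <= 0) {
    warning("zero-trace covariance; returning identity floor")
    return(list(matrix = diag(1e-10, K), rho = 1))
  }
  mu <- tr / K
  tr2 <- sum(cov^2)                       # tr(C^2) for symmetric C
  den <- (n_obs + 1 - 2 / K) * (tr2 - tr^2 / K)
  rho <- if (den <= 0) 1 else min(1, ((1 - 2 / K) * tr2 + tr^2) / den)
  S <- (1 - rho) * cov + rho * mu * diag(K)
  list(matrix = (S + t(S)) / 2, rho = rho)
}

# Eigendecomposition-based symmetric matrix function.
symFun <- function(m, f) {
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  S <- e$vectors %*% (f(e$values) * t(e$vectors))
  (S + t(S)) / 2
}

#' Matrix logarithm of an SPD matrix
#'
#' Via eigendecomposition \eqn{U \, diag(\log \lambda) \, U^T}. Eigenvalues
#' below \code{floor} times the largest are rejected as non-SPD.
#'
#' @param spd SPD matrix.
#' @param floor relative eigenvalue tolerance.
#' @return symmetric matrix logarithm.
#' @export
spdLogm <- function(spd, floor = 1e-10) {
  e <- eigen((spd + t(spd)) / 2, symmetric = TRUE)
  if (min(e$values) <= floor * max(abs(e$values), 1e-300))
    stop("matrix is not positive definite (within tolerance)")
  S <- e$vectors %*% (log(e$values) * t(e$vectors))
  (S + t(S)) / 2
}

#' Matrix exponential of a symmetric matrix
#' @param sym symmetric matrix.
#' @return SPD matrix \eqn{U \, diag(e^\lambda) \, U^T}.
#' @export
symExpm <- function(sym) symFun(sym, exp)

spdSqrt <- function(spd) symFun(spd, function(v) sqrt(pmax(v, 0)))
spdInvSqrt <- function(spd) symFun(spd, function(v) 1 / sqrt(pmax(v, 1e-300)))

#' Log-Euclidean mean of SPD matrices
#'
#' \eqn{expm( t^{-1} \sum_i logm(C_i) )}: the SPD mean under the
#' log-Euclidean metric, used as the tangent-space reference point.
#'
#' @param cov_list nonempty list of SPD matrices of identical dimension.
#' @return SPD mean matrix.
#' @export
logEuclideanMean <- function(cov_list) {
  if (length(cov_list) == 0) stop("empty covariance list")
  acc <- Reduce(`+`, lapply(cov_list, spdLogm))
  symExpm(acc / length(cov_list))
}

#' Project an SPD matrix to the tangent space at a reference
#'
#' \eqn{S = C^{1/2} \, logm(C^{-1/2} \, CM \, C^{-1/2}) \, C^{1/2}} with
#' \eqn{C} the SPD reference; the zero matrix iff \code{cov == reference}.
#'
#' @param cov SPD matrix to project.
#' @param reference SPD reference point (same dimension).
#' @return symmetric tangent matrix.
#' @export
tangentProject <- function(cov, reference) {
  if (!all(dim(cov) == dim(reference))) stop("dimension mismatch")
  Rh <- spdSqrt(reference)
  Rih <- spdInvSqrt(reference)
  S <- Rh %*% spdLogm(Rih %*% cov %*% Rih) %*% Rh
  (S + t(S)) / 2
}

#' Map a tangent matrix back to the SPD manifold
#'
#' Inverse of \code{\link{tangentProject}}:
#' \eqn{C^{1/2} \, expm(C^{-1/2} S C^{-1/2}) \, C^{1/2}}.
#'
#' @param tangent symmetric tangent matrix.
#' @param reference SPD reference point.
#' @return SPD matrix.
#' @export
tangentRetract <- function(tangent, reference) {
  if (!all(dim(tangent) == dim(reference))) stop("dimension mismatch")
  Rh <- spdSqrt(reference)
  Rih <- spdInvSqrt(reference)
  S <- Rh %*% symExpm(Rih %*% tangent %*% Rih) %*% Rh
  (S + t(S)) / 2
}

# Row-major flattening of a K x K matrix to length K^2.
flattenTangent <- function(m) as.vector(t(m))

#' Regularized covariances of every epoch in a band
#'
#' @param banded a \linkS4class{BandedEpochs}.
#' @param band band name or index.
#' @return list of SPD K x K matrices, one per epoch.
#' @export
bandCovariances <- function(banded, band) {
  arr <- banded@bands[[band]]
  n <- dim(arr)[3]
  nObs <- dim(arr)[2]
  lapply(seq_len(n), function(i)
    oasRegularize(covarianceMatrix(arr[, , i]), nObs)$matrix)
}

#' Per-band tangent-space reference points
#'
#' Log-Euclidean mean of the supplied training covariances for each band.
#' References must be computed from training data only and are then frozen
#' for validation/test projection (no test-set leakage).
#'
#' @param cov_by_band named list (band -> list of SPD matrices).
#' @return named list of SPD reference matrices.
#' @export
computeReferences <- function(cov_by_band) {
  lapply(cov_by_band, logEuclideanMean)
}

#' Filter-bank Riemannian feature extraction
#'
#' For each band: epoch covariance, OAS regularization, tangent projection at
#' that band's frozen reference, row-major flattening to a length-K^2 vector
#' (961 for the 31-channel montage).
#'
#' @param banded a \linkS4class{BandedEpochs}.
#' @param references named list of per-band SPD references (training-derived);
#'   names must cover \code{bandNames(banded)}.
#' @param cov_by_band optional precomputed per-band covariance lists (as from
#'   \code{\link{bandCovariances}}) to avoid recomputation.
#' @return a \linkS4class{BandFeatures}.
#' @export
extractFeatures <- function(banded, references, cov_by_band = NULL) {
  bn <- names(banded@bands)
  if (!all(bn %in% names(references)))
    stop("missing reference for band(s): ",
         paste(setdiff(bn, names(references)), collapse = ", "))
  feats <- vector("list", length(bn))
  names(feats) <- bn
  for (b in bn) {
    covs <- if (is.null(cov_by_band)) bandCovariances(banded, b) else cov_by_band[[b]]
    F <- nrow(references[[b]])^2
    M <- matrix(0, length(covs), F)
    for (i in seq_along(covs))
      M[i, ] <- flattenTangent(tangentProject(covs[[i]], references[[b]]))
    feats[[b]] <- M
  }
  new("BandFeatures", features = feats, references = references[bn],
      labels = banded@labels)
}
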