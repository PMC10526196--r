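# Adaptor and critic networks for Wasserstein adversarial domain adaptation.
#
# Layer plans follow the published tables: the adaptor reshapes the length-F
# feature vector to F x 1, applies two 'same'-padded 1-D convolutions
# (kernel 3; 32 then 8 filters; leaky-ReLU + batch norm), flattens (8F) and
# maps densely back to F with a tanh output. The critic maps F densely to 32
# (leaky-ReLU), applies two 'same'-padded kernel-2 convolutions (32 then 64
# filters, leaky-ReLU + batch norm), flattens (2048), then dense 256 -> 64
# (leaky-ReLU) -> 1; output linear by default (Wasserstein critic), sigmoid
# optionally. Widths are configurable for scaled-down experiments; defaults
# are the published plans.

#' Adaptor layer plan
#' @param input_dim feature dimension F (default 961 = 31^2).
#' @param conv_filters two convolution widths (default c(32, 8)).
#' @param kernel convolution kernel size (default 3).
#' @param leaky_alpha leaky-ReLU negative slope.
#' @return adaptor spec list.
#' @export
adaptorSpec <- function(input_dim = 961L, conv_filters = c(32L, 8L),
                        kernel = 3L, leaky_alpha = 0.2) {
  stopifnot(length(conv_filters) == 2, kernel >= 1, input_dim >= kernel)
  list(input_dim = as.integer(input_dim),
       conv_filters = as.integer(conv_filters), kernel = as.integer(kernel),
       leaky_alpha = leaky_alpha)
}

#' Critic layer plan
#' @param input_dim feature dimension F (default 961).
#' @param dense1 width of the first dense layer / conv sequence length
#'   (default 32).
#' @param conv_filters two convolution widths (default c(32, 64)).
#' @param kernel convolution kernel size (default 2).
#' @param fc widths of the two fully-connected layers (default c(256, 64)).
#' @param sigmoid logical; bound the output with a sigmoid (the printed
#'   table) instead of the default linear Wasserstein-critic output.
#' @param leaky_alpha leaky-ReLU negative slope.
#' @return critic spec list.
#' @export
criticSpec <- function(input_dim = 961L, dense1 = 32L,
                       conv_filters = c(32L, 64L), kernel = 2L,
                       fc = c(256L, 64L), sigmoid = FALSE,
                       leaky_alpha = 0.2) {
  stopifnot(length(conv_filters) == 2, length(fc) == 2)
  list(input_dim = as.integer(input_dim), dense1 = as.integer(dense1),
       conv_filters = as.integer(conv_filters), kernel = as.integer(kernel),
       fc = as.integer(fc), sigmoid = isTRUE(sigmoid),
       leaky_alpha = leaky_alpha)
}

#' Expected layer output shapes
#'
#' The per-layer output shapes of a spec, for contract checks against the
#' published plans: at F = 961 the adaptor yields 961x32, 961x8, 7688, 961
#' and the critic 32, 32x32, 32x64, 2048, 256, 64, 1.
#'
#' @param spec an \code{\link{adaptorSpec}} or \code{\link{criticSpec}}.
#' @return list of per-layer shape vectors.
#' @export
layerShapes <- function(spec) {
  if (!is.null(spec$dense1)) {
    L <- spec$dense1
    list(dense1 = L, conv1 = c(L, spec$conv_filters[1]),
         conv2 = c(L, spec$conv_filters[2]),
         flatten = L * spec$conv_filters[2],
         fc1 = spec$fc[1], fc2 = spec$fc[2], out = 1L)
  } else {
    F <- spec$input_dim
    list(conv1 = c(F, spec$conv_filters[1]), conv2 = c(F, spec$conv_filters[2]),
         flatten = F * spec$conv_filters[2], out = F)
  }
}

glorot <- function(nin, nout) {
  matrix(stats::rnorm(nin * nout, 0, sqrt(2 / (nin + nout))), nin, nout)
}

#' Initialize adaptor parameters
#' @param spec an \code{\link{adaptorSpec}}.
#' @param out_dim output dimension (defaults to \code{spec$input_dim}).
#' @return named list of parameter matrices.
#' @export
initAdaptor <- function(spec, out_dim = spec$input_dim) {
  ks <- spec$kernel
  f1 <- spec$conv_filters[1]; f2 <- spec$conv_filters[2]
  F <- spec$input_dim
  list(W1 = glorot(ks, f1), b1 = matrix(0, 1, f1),
       g1 = matrix(1, 1, f1), be1 = matrix(0, 1, f1),
       W2 = glorot(ks * f1, f2), b2 = matrix(0, 1, f2),
       g2 = matrix(1, 1, f2), be2 = matrix(0, 1, f2),
       Wd = glorot(F * f2, out_dim), bd = matrix(0, 1, out_dim))
}

#' Initialize critic parameters
#' @param spec a \code{\link{criticSpec}}.
#' @return named list of parameter matrices.
#' @export
initCritic <- function(spec) {
  ks <- spec$kernel
  L <- spec$dense1
  f1 <- spec$conv_filters[1]; f2 <- spec$conv_filters[2]
  list(Win = glorot(spec$input_dim, L), bin = matrix(0, 1, L),
       W1 = glorot(ks, f1), b1 = matrix(0, 1, f1),
       g1 = matrix(1, 1, f1), be1 = matrix(0, 1, f1),
       W2 = glorot(ks * f1, f2), b2 = matrix(0, 1, f2),
       g2 = matrix(1, 1, f2), be2 = matrix(0, 1, f2),
       Wf1 = glorot(L * f2, spec$fc[1]), bf1 = matrix(0, 1, spec$fc[1]),
       Wf2 = glorot(spec$fc[1], spec$fc[2]), bf2 = matrix(0, 1, spec$fc[2]),
       Wo = glorot(spec$fc[2], 1L), bo = matrix(0, 1, 1))
}

# ---- building blocks (node-in, node-out) ---------------------------------

nnBias <- function(h, b) {            # broadcast 1 x C bias over rows
  n <- nrow(adValue(h))
  adAdd(h, adMatmul(matrix(1, n, 1), b))
}

nnDense <- function(x, W, b) adAffine(x, W, b)

# batch norm over rows, per column; gamma/beta 1 x C
nnBatchNorm <- function(h, gamma, beta, eps = 1e-5) {
  n <- nrow(adValue(h))
  meanRow <- matrix(1 / n, 1, n)
  mu <- adMatmul(meanRow, h)                              # 1 x C
  hc <- adSubRow(h, mu)
  v <- adMatmul(meanRow, adMul(hc, hc))
  invs <- adPowC(adAddC(v, eps), -0.5)
  adRowScaleShift(adRowScale(hc, invs), gamma, beta)
}

# 'same'-padded 1-D convolution on position-major (n x L*C_in) input.
# Odd kernels pad (k-1)/2 both sides; even kernels pad the extra zero on the
# right. Returns grouped (n*L x C_out) activations.
nnConv1d <- function(x, L, C_in, W, b, kernel) {
  adAffine(adPatchGather(x, L, C_in, kernel), W, b)
}

#' Adaptor forward pass
#' @param params parameter list from \code{\link{initAdaptor}}.
#' @param x input: n x F matrix or adnode.
#' @param spec the \code{\link{adaptorSpec}}.
#' @return adnode, n x out_dim in (-1, 1).
#' @export
adaptorForward <- function(params, x, spec) {
  x <- adWrap(x)
  n <- nrow(adValue(x))
  F <- spec$input_dim
  al <- spec$leaky_alpha
  p <- lapply(params, adWrap)
  h <- nnConv1d(x, F, 1L, p$W1, p$b1, spec$kernel)        # (nF x f1)
  h <- nnBatchNorm(adLeakyRelu(h, al), p$g1, p$be1)
  h <- adChanMerge(h, n, F, spec$conv_filters[1])
  h <- nnConv1d(h, F, spec$conv_filters[1], p$W2, p$b2, spec$kernel)
  h <- nnBatchNorm(adLeakyRelu(h, al), p$g2, p$be2)
  h <- adChanMerge(h, n, F, spec$conv_filters[2])         # (n x F*f2)
  adTanh(nnDense(h, p$Wd, p$bd))
}

#' Critic forward pass
#' @param params parameter list from \code{\link{initCritic}}.
#' @param x input: n x F matrix or adnode.
#' @param spec the \code{\link{criticSpec}}.
#' @return adnode, n x 1 score.
#' @export
criticForward <- function(params, x, spec) {
  x <- adWrap(x)
  n <- nrow(adValue(x))
  al <- spec$leaky_alpha
  L <- spec$dense1
  p <- lapply(params, adWrap)
  h <- adLeakyRelu(nnDense(x, p$Win, p$bin), al)          # (n x L), 1 channel
  h <- nnConv1d(h, L, 1L, p$W1, p$b1, spec$kernel)
  h <- nnBatchNorm(adLeakyRelu(h, al), p$g1, p$be1)
  h <- adChanMerge(h, n, L, spec$conv_filters[1])
  h <- nnConv1d(h, L, spec$conv_filters[1], p$W2, p$b2, spec$kernel)
  h <- nnBatchNorm(adLeakyRelu(h, al), p$g2, p$be2)
  h <- adChanMerge(h, n, L, spec$conv_filters[2])         # (n x L*f2)
  h <- adLeakyRelu(nnDense(h, p$Wf1, p$bf1), al)
  h <- adLeakyRelu(nnDense(h, p$Wf2, p$bf2), al)
  out <- nnDense(h, p$Wo, p$bo)
  if (spec$sigmoid) adSigmoid(out) else out
}

# ---- Adam ----------------------------------------------------------------

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adamStep <- function(params, grads, state, lr = 0.001, beta1 = 0.9,
                     beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
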