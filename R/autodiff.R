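# Minimal reverse-mode automatic differentiation on matrices.
#
# Nodes are environments holding a value, parent nodes and one
# vector-Jacobian-product closure per parent. VJP closures are written in
# terms of these same primitives, so gradients are themselves differentiable
# graphs: the second-order derivatives needed by the Wasserstein gradient
# penalty come out of an ordinary second backward pass. Values are computed
# eagerly; node ids increase at creation, giving a ready topological order
# for the backward sweep.

.adState <- new.env(parent = emptyenv())
.adState$counter <- 0

adNode <- function(val, parents = list(), vjps = list()) {
  id <- .adState$counter + 1
  .adState$counter <- id
  e <- new.env(parent = emptyenv())
  e$val <- val
  e$parents <- parents
  e$vjps <- vjps
  e$id <- id
  class(e) <- "adnode"
  e
}

isAdNode <- function(x) is.environment(x)   # nodes are the only environments here
adWrap <- function(x) {
  if (isAdNode(x)) return(x)
  if (!is.matrix(x)) x <- matrix(x, 1, 1)
  adNode(x)
}
adValue <- function(x) if (isAdNode(x)) x$val else x

# ---- primitives ----------------------------------------------------------

adMatmul <- function(a, b) {
  a <- adWrap(a); b <- adWrap(b)
  adNode(a$val %*% b$val, list(a, b),
         list(function(g) adMatmul(g, adT(b)),
              function(g) adMatmul(adT(a), g)))
}

adT <- function(a) {
  a <- adWrap(a)
  adNode(t(a$val), list(a), list(function(g) adT(g)))
}

adAdd <- function(a, b) {
  a <- adWrap(a); b <- adWrap(b)
  adNode(a$val + b$val, list(a, b),
         list(function(g) g, function(g) g))
}

adSub <- function(a, b) {
  a <- adWrap(a); b <- adWrap(b)
  adNode(a$val - b$val, list(a, b),
         list(function(g) g, function(g) adScale(g, -1)))
}

adMul <- function(a, b) {
  a <- adWrap(a); b <- adWrap(b)
  adNode(a$val * b$val, list(a, b),
         list(function(g) adMul(g, b), function(g) adMul(g, a)))
}

adScale <- function(a, k) {           # k plain scalar
  a <- adWrap(a)
  adNode(a$val * k, list(a), list(function(g) adScale(g, k)))
}

adAddC <- function(a, c) {            # c plain scalar or matrix constant
  a <- adWrap(a)
  adNode(a$val + c, list(a), list(function(g) g))
}

adPowC <- function(a, p) {            # a > 0 elementwise for fractional p
  a <- adWrap(a)
  adNode(a$val^p, list(a),
         list(function(g) adMul(g, adScale(adPowC(a, p - 1), p))))
}

adTanh <- function(a) {
  a <- adWrap(a)
  out <- adNode(tanh(a$val), list(a), list(NULL))
  out$vjps[[1]] <- function(g) adMul(g, adAddC(adScale(adMul(out, out), -1), 1))
  out
}

adSigmoid <- function(a) {
  a <- adWrap(a)
  out <- adNode(1 / (1 + exp(-a$val)), list(a), list(NULL))
  out$vjps[[1]] <- function(g)
    adMul(g, adMul(out, adAddC(adScale(out, -1), 1)))
  out
}

adLeakyRelu <- function(a, alpha = 0.2) {
  a <- adWrap(a)
  pos <- a$val > 0                       # constant a.e.: 2nd derivative zero
  mask <- pos + alpha * !pos
  adNode(a$val * mask, list(a), list(function(g) adMul(g, mask)))
}

adSum <- function(a) {
  a <- adWrap(a)
  d <- dim(a$val)
  adNode(matrix(sum(a$val), 1, 1), list(a),
         list(function(g) adBcast(g, d[1], d[2])))
}

adBcast <- function(a, n, m) {        # broadcast a 1x1 node to n x m
  a <- adWrap(a)
  adNode(matrix(a$val[1, 1], n, m), list(a), list(function(g) adSum(g)))
}

adCols <- function(a, idx) {          # column selection, constant index
  a <- adWrap(a)
  nc <- ncol(a$val)
  adNode(a$val[, idx, drop = FALSE], list(a),
         list(function(g) adUncols(g, idx, nc)))
}

adUncols <- function(a, idx, ncol_out) {  # scatter columns into zeros
  a <- adWrap(a)
  stopifnot(!anyDuplicated(idx))
  out <- matrix(0, nrow(a$val), ncol_out)
  out[, idx] <- a$val
  adNode(out, list(a), list(function(g) adCols(g, idx)))
}

# (n x L*C) -> (n*L x C): row (t-1)*n + i holds sample i, position t.
# Column layout of the input is position-major: col (t-1)*C + c.
adChanSplit <- function(a, L, C) {
  a <- adWrap(a)
  n <- nrow(a$val)
  out <- matrix(0, n * L, C)
  for (c in seq_len(C))
    out[, c] <- as.vector(a$val[, seq(c, L * C, by = C), drop = FALSE])
  adNode(out, list(a), list(function(g) adChanMerge(g, n, L, C)))
}

# inverse: (n*L x C) -> (n x L*C)
adChanMerge <- function(a, n, L, C) {
  a <- adWrap(a)
  out <- matrix(0, n, L * C)
  for (c in seq_len(C))
    out[, seq(c, L * C, by = C)] <- matrix(a$val[, c], n, L)
  adNode(out, list(a), list(function(g) adChanSplit(g, L, C)))
}

adMean <- function(a) adScale(adSum(a), 1 / length(adValue(a)))

# mean over rows of a column vector / matrix (scalar output)
adRowSums <- function(a) {            # (n x m) -> (n x 1)
  a <- adWrap(a)
  adMatmul(a, matrix(1, ncol(a$val), 1))
}

# ---- backward ------------------------------------------------------------

# Gradient of a scalar-valued root with respect to the listed nodes.
# Returns adnodes (differentiable), so calling adGrad on expressions built
# from its outputs yields higher-order derivatives.
adGrad <- function(root, wrt) {
  stopifnot(isAdNode(root), length(root$val) == 1)
  # Reachable nodes, addressed by creation id (dense integer offsets).
  maxId <- root$id
  minId <- maxId
  stack <- vector("list", 64L)
  stack[[1L]] <- root
  root$.mark <- TRUE
  top <- 1L
  nodes <- list()
  nn <- 0L
  while (top > 0L) {
    nd <- stack[[top]]
    top <- top - 1L
    nn <- nn + 1L
    nodes[[nn]] <- nd
    if (nd$id < minId) minId <- nd$id
    for (p in nd$parents)
      if (isAdNode(p) && is.null(p$.mark)) {
        p$.mark <- TRUE
        top <- top + 1L
        stack[[top]] <- p
      }
  }
  ord <- order(vapply(nodes, function(n) n$id, 0), decreasing = TRUE)
  span <- maxId - minId + 1
  grads <- vector("list", span)
  grads[[root$id - minId + 1]] <- adWrap(matrix(1, 1, 1))
  for (j in ord) {
    nd <- nodes[[j]]
    nd$.mark <- NULL
    g <- grads[[nd$id - minId + 1]]
    if (is.null(g)) next
    ps <- nd$parents
    for (i in seq_along(ps)) {
      p <- ps[[i]]
      if (!isAdNode(p)) next
      contrib <- nd$vjps[[i]](g)
      off <- p$id - minId + 1
      gp <- grads[[off]]
      grads[[off]] <- if (is.null(gp)) contrib else adAdd(gp, contrib)
    }
  }
  lapply(wrt, function(w) {
    g <- if (w$id >= minId) grads[[w$id - minId + 1]] else NULL
    if (is.null(g)) adWrap(matrix(0, nrow(w$val), ncol(w$val))) else g
  })
}

# ---- fused ops (fewer nodes on the training hot path) --------------------

# X W + 1 b  (dense layer in one node); b is 1 x C
adAffine <- function(x, W, b) {
  x <- adWrap(x); W <- adWrap(W); b <- adWrap(b)
  n <- nrow(x$val)
  adNode(x$val %*% W$val + matrix(b$val, n, ncol(W$val), byrow = TRUE),
         list(x, W, b),
         list(function(g) adMatmul(g, adT(W)),
              function(g) adMatmul(adT(x), g),
              function(g) adMatmul(matrix(1, 1, nrow(g$val)), g)))
}

# X - 1 mu (subtract a 1 x C row from every row)
adSubRow <- function(x, mu) {
  x <- adWrap(x); mu <- adWrap(mu)
  n <- nrow(x$val)
  adNode(x$val - matrix(mu$val, n, ncol(x$val), byrow = TRUE),
         list(x, mu),
         list(function(g) g,
              function(g) adScale(adMatmul(matrix(1, 1, nrow(g$val)), g), -1)))
}

# X * (1 s) (scale every row elementwise by the 1 x C row s)
adRowScale <- function(x, s) {
  x <- adWrap(x); s <- adWrap(s)
  n <- nrow(x$val)
  adNode(x$val * matrix(s$val, n, ncol(x$val), byrow = TRUE),
         list(x, s),
         list(function(g) adRowScale(g, s),
              function(g) adMatmul(matrix(1, 1, nrow(g$val)), adMul(g, x))))
}

# X * (1 s) + 1 b (batch-norm scale-and-shift in one node)
adRowScaleShift <- function(x, s, b) {
  x <- adWrap(x); s <- adWrap(s); b <- adWrap(b)
  n <- nrow(x$val)
  adNode(x$val * matrix(s$val, n, ncol(x$val), byrow = TRUE) +
           matrix(b$val, n, ncol(x$val), byrow = TRUE),
         list(x, s, b),
         list(function(g) adRowScale(g, s),
              function(g) adMatmul(matrix(1, 1, nrow(g$val)), adMul(g, x)),
              function(g) adMatmul(matrix(1, 1, nrow(g$val)), g)))
}

# Fused same-padded im2col pair: gather emits the (n*L x ks*C) patch matrix
# (row (t-1)*n+i; column (k-1)*C+c), scatter is its exact adjoint. A whole
# convolution is then gather + affine, which keeps the training graph small.
patchIndex <- function(n, L, C, kernel) {
  padL <- (kernel - 1L) %/% 2L
  Lp <- L + kernel - 1L
  list(padL = padL, Lp = Lp)
}

adPatchGather <- function(x, L, C, kernel) {
  x <- adWrap(x)
  n <- nrow(x$val)
  pi <- patchIndex(n, L, C, kernel)
  xp <- matrix(0, n, pi$Lp * C)
  xp[, pi$padL * C + seq_len(L * C)] <- x$val
  P <- matrix(0, n * L, kernel * C)
  for (k in seq_len(kernel)) {
    for (c in seq_len(C)) {
      cols <- ((k - 1L) + seq_len(L) - 1L) * C + c
      P[, (k - 1L) * C + c] <- as.vector(xp[, cols, drop = FALSE])
    }
  }
  adNode(P, list(x), list(function(g) adPatchScatter(g, n, L, C, kernel)))
}

adPatchScatter <- function(p, n, L, C, kernel) {
  p <- adWrap(p)
  pi <- patchIndex(n, L, C, kernel)
  xp <- matrix(0, n, pi$Lp * C)
  for (k in seq_len(kernel)) {
    for (c in seq_len(C)) {
      cols <- ((k - 1L) + seq_len(L) - 1L) * C + c
      xp[, cols] <- xp[, cols] + matrix(p$val[, (k - 1L) * C + c], n, L)
    }
  }
  out <- xp[, pi$padL * C + seq_len(L * C), drop = FALSE]
  adNode(out, list(p), list(function(g) adPatchGather(g, L, C, kernel)))
}
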