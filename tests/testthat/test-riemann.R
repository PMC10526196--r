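test_that("epoch covariance matches the brute-force outer-product oracle", {
  X <- matrix(c(1, -1, 1, -1), 2, 2, byrow = TRUE)
  expect_equal(covarianceMatrix(X), matrix(2, 2, 2))
  expect_equal(covarianceMatrix(matrix(0, 3, 10)), matrix(0, 3, 3))
  set.seed(4)
  for (r in 1:5) {
    K <- sample(2:6, 1); N <- sample(10:40, 1)
    X <- matrix(rnorm(K * N), K, N)
    brute <- matrix(0, K, K)
    for (i in seq_len(N)) brute <- brute + X[, i] %*% t(X[, i])
    brute <- brute / (N - 1)
    expect_lt(max(abs(covarianceMatrix(X) - brute)), 1e-10)
  }
  expect_error(covarianceMatrix(matrix(1, 3, 1)), "two time points")
})

test_that("OAS shrinkage yields SPD matrices with the expected limits", {
  # shrinkage target equals input: identity is a fixed point
  expect_equal(oasRegularize(diag(4), 100)$matrix, diag(4))
  # rank-deficient covariance becomes positive definite
  X <- matrix(rnorm(3 * 2), 3, 2)
  C <- covarianceMatrix(X)
  reg <- oasRegularize(C, 2)
  expect_gt(min(eigen(reg$matrix, symmetric = TRUE)$values), 0)
  expect_true(reg$rho >= 0 && reg$rho <= 1)
  # trace is preserved by the convex combination
  expect_equal(sum(diag(reg$matrix)), sum(diag(C)))
  # the intensity vanishes as observations grow
  set.seed(9)
  C2 <- randomSPD(5)
  rhos <- sapply(c(10, 1e3, 1e6), function(n) oasRegularize(C2, n)$rho)
  expect_true(all(diff(rhos) < 0))
  expect_lt(rhos[3], 1e-4)
  expect_lt(relFrob(oasRegularize(C2, 1e6)$matrix, C2), 1e-3)
  expect_warning(oasRegularize(matrix(0, 3, 3), 10), "zero-trace")
})

test_that("matrix log/exp agree with a Taylor-series oracle and invert", {
  expect_equal(spdLogm(diag(3)), matrix(0, 3, 3))
  expect_equal(symExpm(matrix(0, 3, 3)), diag(3))
  set.seed(21)
  for (r in 1:10) {
    K <- sample(2:8, 1)
    S <- randomSPD(K)
    expect_lt(relFrob(symExpm(spdLogm(S)), S), 1e-8)
    A <- spdLogm(S)
    expect_lt(relFrob(symExpm(A), expmTaylor(A)), 1e-8)
  }
  expect_error(spdLogm(diag(c(1, -1))), "not positive definite")
})

test_that("log-Euclidean mean reduces to geometric means and stays SPD", {
  A <- randomSPD(4, seed = 2)
  expect_lt(relFrob(logEuclideanMean(list(A, A, A)), A), 1e-10)
  expect_equal(logEuclideanMean(list(diag(2), diag(c(4, 4)))), diag(c(2, 2)))
  set.seed(3)
  covs <- lapply(1:6, function(i) randomSPD(5))
  M <- logEuclideanMean(covs)
  expect_gt(min(eigen(M, symmetric = TRUE)$values), 0)
  # permutation invariance
  expect_lt(relFrob(logEuclideanMean(rev(covs)), M), 1e-10)
  expect_error(logEuclideanMean(list()), "empty")
})

test_that("tangent projection and retraction are mutual inverses", {
  R <- randomSPD(3, seed = 5)
  expect_lt(max(abs(tangentProject(R, R))), 1e-10)
  expect_lt(relFrob(tangentRetract(matrix(0, 3, 3), R), R), 1e-12)
  # scalar case: log of the ratio
  expect_equal(tangentProject(matrix(4), matrix(1))[1, 1], log(4))
  expect_equal(tangentRetract(matrix(log(4)), matrix(1))[1, 1], 4)
  set.seed(6)
  for (r in 1:100) {
    K <- sample(2:8, 1)
    C <- randomSPD(K); R <- randomSPD(K)
    S <- tangentProject(C, R)
    expect_lt(relFrob(tangentRetract(S, R), C), 1e-8)
  }
  expect_error(tangentProject(randomSPD(3), randomSPD(4)), "dimension")
})

test_that("feature extraction flattens to K^2 and respects channel permutation", {
  es <- flatEpochSet(6, K = 4, T = 60)
  banded <- asBroadbandBank(es)
  covs <- list(broadband = bandCovariances(banded, "broadband"))
  refs <- computeReferences(covs)
  fe <- extractFeatures(banded, refs, covs)
  expect_identical(dim(bandFeatureMatrix(fe, "broadband")), c(6L, 16L))
  # epochs identical to the reference give near-zero features
  one <- subsetEpochSetForTest(es, 1)
  b1 <- asBroadbandBank(one)
  c1 <- list(broadband = bandCovariances(b1, "broadband"))
  fe1 <- extractFeatures(b1, computeReferences(c1), c1)
  expect_lt(max(abs(bandFeatureMatrix(fe1, "broadband"))), 1e-8)
  # equivariance under simultaneous channel permutation
  perm <- c(3, 1, 4, 2)
  esP <- new("EpochSet", epochs = es@epochs[perm, , , drop = FALSE],
             fs = es@fs, labels = es@labels, channels = es@channels[perm])
  bP <- asBroadbandBank(esP)
  cP <- list(broadband = bandCovariances(bP, "broadband"))
  feP <- extractFeatures(bP, computeReferences(cP), cP)
  m <- matrix(bandFeatureMatrix(fe, "broadband")[2, ], 4, 4, byrow = TRUE)
  mP <- matrix(bandFeatureMatrix(feP, "broadband")[2, ], 4, 4, byrow = TRUE)
  expect_lt(max(abs(mP - m[perm, perm])), 1e-8)
  # missing band reference is caught
  expect_error(extractFeatures(banded, list(), covs), "missing reference")
})

test_that("the 31-channel montage yields length-961 features", {
  set.seed(8)
  arr <- array(rnorm(31 * 40 * 3), c(31, 40, 3))
  es <- new("EpochSet", epochs = arr, fs = 500,
            labels = data.frame(subject = "S01", modality = "audio",
                                emotion = "pleasure", trial = 1:3, window = 1L),
            channels = sprintf("CH%02d", 1:31))
  banded <- asBroadbandBank(es)
  covs <- list(broadband = bandCovariances(banded, "broadband"))
  fe <- extractFeatures(banded, computeReferences(covs), covs)
  expect_identical(ncol(bandFeatureMatrix(fe, "broadband")), 961L)
})
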