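test_that("the feature scaler maps into [-1,1] and inverts exactly", {
  # full-range features give an identity-like map
  x <- matrix(c(-1, 1, 0.5, -1, 0, 1), 3, 2)
  sc <- fitFeatureScaler(x)
  expect_lt(max(abs(applyScaler(sc, x) - x)), 1e-12)
  set.seed(1)
  y <- matrix(rnorm(50), 10, 5) * 3 + 2
  sc2 <- fitFeatureScaler(y)
  expect_lt(max(abs(invertScaler(sc2, applyScaler(sc2, y)) - y)), 1e-10)
  expect_true(all(abs(applyScaler(sc2, y)) <= 1 + 1e-12))
  # documented affine example: min -2, max 2 -> value 1 maps to 0.5
  sc3 <- fitFeatureScaler(matrix(c(-2, 2), 2, 1))
  expect_equal(applyScaler(sc3, matrix(1, 1, 1))[1, 1], 0.5)
  # constant dimension maps to 0 with a safe inverse
  sc4 <- fitFeatureScaler(matrix(5, 4, 1))
  expect_equal(applyScaler(sc4, matrix(5, 2, 1)), matrix(0, 2, 1))
  expect_equal(invertScaler(sc4, matrix(0, 2, 1)), matrix(5, 2, 1))
})

test_that("the gradient penalty matches closed forms for linear critics", {
  set.seed(5)
  F <- 6; n <- 8
  w <- matrix(rnorm(F), F, 1)
  w <- w / sqrt(sum(w^2))
  xt <- matrix(rnorm(n * F), n, F)
  xa <- matrix(rnorm(n * F), n, F)
  u <- runif(n)
  # unit-norm linear critic: gradient norm 1 everywhere -> penalty 0
  lin <- function(z) fbadr:::adMatmul(z, w)
  expect_lt(gradientPenalty(lin, xt, xa, u), 1e-12)
  # doubled critic -> (2-1)^2 = 1
  lin2 <- function(z) fbadr:::adScale(fbadr:::adMatmul(z, w), 2)
  expect_equal(gradientPenalty(lin2, xt, xa, u), 1.0)
  # constant critic -> (0-1)^2 = 1
  const <- function(z) fbadr:::adScale(fbadr:::adMatmul(z, matrix(0, F, 1)), 1)
  expect_equal(gradientPenalty(const, xt, xa, u), 1.0, tolerance = 1e-4)
})

test_that("network layer shapes match the published plans", {
  as <- layerShapes(adaptorSpec())
  expect_identical(as$conv1, c(961L, 32L))
  expect_identical(as$conv2, c(961L, 8L))
  expect_identical(as$flatten, 7688L)
  expect_identical(as$out, 961L)
  cs <- layerShapes(criticSpec())
  expect_identical(cs$dense1, 32L)
  expect_identical(cs$conv1, c(32L, 32L))
  expect_identical(cs$conv2, c(32L, 64L))
  expect_identical(cs$flatten, 2048L)
  expect_identical(cs$fc1, 256L)
  expect_identical(cs$fc2, 64L)
  expect_identical(cs$out, 1L)
  # realized parameter tensors agree with the plans
  set.seed(1)
  ap <- initAdaptor(adaptorSpec())
  expect_identical(dim(ap$W1), c(3L, 32L))      # kernel 3, 32 filters
  expect_identical(dim(ap$W2), c(96L, 8L))      # kernel 3 x 32 in, 8 filters
  expect_identical(dim(ap$Wd), c(7688L, 961L))
  cp <- initCritic(criticSpec())
  expect_identical(dim(cp$Win), c(961L, 32L))
  expect_identical(dim(cp$W2), c(64L, 64L))     # kernel 2 x 32 in, 64 filters
  expect_identical(dim(cp$Wf1), c(2048L, 256L))
  expect_identical(dim(cp$Wo), c(64L, 1L))
  # a forward pass at full width emits 961-dimensional tanh-bounded output
  x <- matrix(rnorm(2 * 961), 2, 961)
  out <- fbadr:::adValue(adaptorForward(ap, x, adaptorSpec()))
  expect_identical(dim(out), c(2L, 961L))
  expect_true(all(abs(out) < 1))
  d <- fbadr:::adValue(criticForward(cp, x, criticSpec()))
  expect_identical(dim(d), c(2L, 1L))
})

test_that("adaptation requires target coverage of every source class", {
  x <- matrix(rnorm(40), 10, 4)
  expect_error(
    trainAdaptation(x, rep("pleasure", 10), x,
                    rep(c("pleasure", "unpleasure"), 5),
                    adaptorSpec(input_dim = 4L, conv_filters = c(2L, 2L)),
                    criticSpec(input_dim = 4L, dense1 = 4L,
                               conv_filters = c(2L, 2L), fc = c(4L, 2L))),
    "absent in target")
})

test_that("adapted features are shape-preserving, bounded and deterministic", {
  set.seed(2)
  n <- 24
  xt <- matrix(runif(n * 6, -1, 1), n, 6)
  xs <- matrix(runif(n * 6, -1, 1), n, 6)
  y <- rep(c("pleasure", "unpleasure"), n / 2)
  aspec <- adaptorSpec(input_dim = 6L, conv_filters = c(3L, 2L))
  cspec <- criticSpec(input_dim = 6L, dense1 = 6L, conv_filters = c(3L, 3L),
                      fc = c(8L, 4L))
  cfg <- adaptTrainConfig(epochs = 3L, batch = 12L, seed = 9L)
  m <- trainAdaptation(xt, y, xs, y, aspec, cspec, cfg)
  expect_identical(nrow(lossHistory(m)), 3L)
  out <- adaptFeatures(m, xs, y)
  expect_identical(dim(out), dim(xs))
  expect_true(all(abs(out) < 1))
  expect_identical(out, adaptFeatures(m, xs, y))
  # bitwise training reproducibility under a fixed seed
  m2 <- trainAdaptation(xt, y, xs, y, aspec, cspec, cfg)
  expect_identical(m@adaptors, m2@adaptors)
  expect_identical(lossHistory(m), lossHistory(m2))
  expect_error(adaptFeatures(m, xs[, 1:3], y), "dimension mismatch")
})

test_that("one-hot conditioning trains a single label-aware pair", {
  set.seed(3)
  n <- 16
  xt <- matrix(runif(n * 4, -1, 1), n, 4)
  xs <- matrix(runif(n * 4, -1, 1), n, 4)
  y <- rep(c("pleasure", "unpleasure"), n / 2)
  aspec <- adaptorSpec(input_dim = 6L, conv_filters = c(2L, 2L), kernel = 2L)
  cspec <- criticSpec(input_dim = 6L, dense1 = 4L, conv_filters = c(2L, 2L),
                      fc = c(4L, 2L))
  cfg <- adaptTrainConfig(epochs = 2L, batch = 8L, seed = 1L,
                          conditioning = "onehot")
  m <- trainAdaptation(xt, y, xs, y, aspec, cspec, cfg)
  expect_identical(names(m@adaptors), "all")
  out <- adaptFeatures(m, xs, y)
  expect_identical(dim(out), c(as.integer(n), 4L))
})

test_that("adaptation recovers a mean-shifted toy distribution", {
  set.seed(11)
  n <- 64
  xt <- cbind(rnorm(n), rnorm(n))
  xs <- cbind(rnorm(n) + 3, rnorm(n))
  aspec <- adaptorSpec(input_dim = 2L, conv_filters = c(4L, 2L), kernel = 2L)
  cspec <- criticSpec(input_dim = 2L, dense1 = 8L, conv_filters = c(4L, 4L),
                      fc = c(16L, 8L))
  # toy-scale training settings: stronger learning rate and a light penalty
  # suit the 2-dimensional critic (see the methods vignette)
  cfg <- adaptTrainConfig(epochs = 100L, batch = 32L, lr = 0.003,
                          lambda_gp = 1, seed = 2L)
  m <- trainAdaptation(xt, rep("pleasure", n), xs, rep("pleasure", n),
                       aspec, cspec, cfg)
  xad <- invertScaler(m@scaler, adaptFeatures(m, xs, rep("pleasure", n)))
  d0 <- sqrt(sum((colMeans(xs) - colMeans(xt))^2))
  d1 <- sqrt(sum((colMeans(xad) - colMeans(xt))^2))
  expect_gte(1 - d1 / d0, 0.8)    # >= 80% of the mean discrepancy removed
})
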