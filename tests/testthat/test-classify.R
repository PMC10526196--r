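mkFeatureToy <- function(n = 40, sep = 4, seed = 1) {
  set.seed(seed)
  y <- rep(c("pleasure", "unpleasure"), each = n / 2)
  x <- cbind(rnorm(n) + ifelse(y == "pleasure", sep / 2, -sep / 2), rnorm(n))
  list(x = x, y = y)
}

test_that("accuracy equals the confusion-count and counting oracles", {
  expect_equal(classificationAccuracy(rep("pleasure", 10),
                                      rep("pleasure", 10)), 1.0)
  # TP=3 TN=2 FP=1 FN=2 -> 5/8
  pred <- c("pleasure", "pleasure", "pleasure", "pleasure",
            "unpleasure", "unpleasure", "unpleasure", "unpleasure")
  truth <- c("pleasure", "pleasure", "pleasure", "unpleasure",
             "pleasure", "pleasure", "unpleasure", "unpleasure")
  expect_equal(classificationAccuracy(pred, truth), 0.625)
  cc <- confusionCounts(pred, truth)
  expect_equal(unname(cc), c(3, 2, 2, 1))
  expect_equal(unname((cc["TP"] + cc["TN"]) / sum(cc)), 0.625)
  expect_equal(classificationAccuracy(rep("pleasure", 4),
                                      rep("unpleasure", 4)), 0.0)
  set.seed(2)
  for (r in 1:20) {
    n <- sample(5:50, 1)
    p <- sample(c("pleasure", "unpleasure"), n, replace = TRUE)
    t <- sample(c("pleasure", "unpleasure"), n, replace = TRUE)
    count <- 0
    for (i in seq_len(n)) count <- count + (p[i] == t[i])
    expect_equal(classificationAccuracy(p, t), count / n)
  }
  expect_error(classificationAccuracy(character(), character()), "nonempty")
})

test_that("band SVMs separate a separable toy and fail on one class", {
  toy <- mkFeatureToy(sep = 6)
  feats <- list(b1 = toy$x, b2 = toy$x)
  svms <- trainBandSvms(feats, toy$y)
  for (b in names(svms))
    expect_equal(mean(predict(svms[[b]], toy$x) == toy$y), 1.0)
  # identical features in two bands give identical predictions
  expect_identical(as.character(predict(svms$b1, toy$x)),
                   as.character(predict(svms$b2, toy$x)))
  expect_error(trainBandSvms(feats, rep("pleasure", 40)), "single class")
})

test_that("shuffled labels give chance-level held-out accuracy", {
  set.seed(7)
  accs <- replicate(8, {
    n <- 200
    x <- matrix(rnorm(n * 4), n, 4)
    y <- sample(rep(c("pleasure", "unpleasure"), n / 2))
    tr <- sample(n, n / 2)
    svms <- trainBandSvms(list(b = x[tr, ]), y[tr])
    mean(predict(svms$b, x[-tr, ]) == y[-tr])
  })
  expect_lt(abs(mean(accs) - 0.5), 0.1)
})

test_that("the LR meta-classifier blends band predictions sensibly", {
  # unanimous perfect bands -> perfect ensemble
  truth <- rep(c("pleasure", "unpleasure"), each = 20)
  perfect <- as.integer(truth == "pleasure")
  bp <- matrix(rep(perfect, 6), ncol = 6)
  meta <- trainMeta(bp, truth)
  pred <- fbadr:::metaPredict(meta, bp, c("pleasure", "unpleasure"))
  expect_equal(classificationAccuracy(pred, truth), 1.0)
  # five random bands + one perfect, n_v = 200 -> LR finds the good band
  set.seed(3)
  truth2 <- rep(c("pleasure", "unpleasure"), each = 100)
  bp2 <- cbind(matrix(rbinom(200 * 5, 1, 0.5), 200, 5),
               as.integer(truth2 == "pleasure"))
  meta2 <- trainMeta(bp2, truth2)
  pred2 <- fbadr:::metaPredict(meta2, bp2, c("pleasure", "unpleasure"))
  expect_gte(classificationAccuracy(pred2, truth2), 0.95)
  # majority-consistent band votes follow the majority
  set.seed(4)
  truth3 <- rep(c("pleasure", "unpleasure"), each = 50)
  flip <- function(v, p) ifelse(runif(length(v)) < p, 1L - v, v)
  base3 <- as.integer(truth3 == "pleasure")
  bp3 <- sapply(1:6, function(i) flip(base3, 0.15))
  meta3 <- trainMeta(bp3, truth3)
  probe <- rbind(rep(1L, 6), rep(0L, 6))
  pred3 <- fbadr:::metaPredict(meta3, probe, c("pleasure", "unpleasure"))
  expect_identical(unname(pred3), c("pleasure", "unpleasure"))
  expect_error(trainMeta(bp, rep("pleasure", 40)), "single class")
})

test_that("the full ensemble predicts trained points and is deterministic", {
  toy <- mkFeatureToy(sep = 6)
  feats <- lapply(1:6, function(i) toy$x)
  names(feats) <- paste0("band", 1:6)
  model <- trainEnsemble(feats, toy$y, feats, toy$y)
  pred <- predictEnsemble(model, feats)
  expect_equal(classificationAccuracy(pred, toy$y), 1.0)
  expect_identical(pred, predictEnsemble(model, feats))
  expect_error(predictEnsemble(model, feats[1:5]), "missing band")
})
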