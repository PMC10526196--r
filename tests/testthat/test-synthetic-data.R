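test_that("emotion covariances coincide at zero separation and diverge monotonically", {
  cfg0 <- tinyGenConfig(class_sep = 0)
  for (b in c(1L, 4L)) {
    expect_identical(makeBandCovariances(cfg0, b, "pleasure"),
                     makeBandCovariances(cfg0, b, "unpleasure"))
  }
  cfg1 <- tinyGenConfig(class_sep = 1)
  cfg2 <- tinyGenConfig(class_sep = 2)
  for (b in 1:6) {
    d1 <- norm(makeBandCovariances(cfg1, b, "pleasure") -
               makeBandCovariances(cfg1, b, "unpleasure"), "F")
    d2 <- norm(makeBandCovariances(cfg2, b, "pleasure") -
               makeBandCovariances(cfg2, b, "unpleasure"), "F")
    expect_gt(d2, d1)
    ev <- eigen(makeBandCovariances(cfg1, b, "pleasure"), symmetric = TRUE)$values
    expect_gt(min(ev), 0)
  }
  expect_error(makeBandCovariances(cfg1, 7, "pleasure"), "band_index")
})

test_that("a long single-band trial recovers its generating covariance", {
  # the gamma band is widest, giving the most effective samples (~2 BW T)
  # per unit duration for the law-of-large-numbers check
  cfg <- tinyGenConfig(sensor_noise = 0, subject_jitter = 0, trial_s = 60,
                       pre_s = 0, active_bands = 6L, class_sep = 1)
  r <- simulateTrial(cfg, 1, "audio", "pleasure")
  emp <- tcrossprod(sweep(r@data, 1, rowMeans(r@data))) / (ncol(r@data) - 1)
  gen <- makeBandCovariances(cfg, 6L, "pleasure")
  expect_lt(relFrob(emp, gen), 0.10)
})

test_that("zero shift produces modality-exchangeable covariances, nonzero does not", {
  covOf <- function(config, mod) {
    r <- simulateTrial(config, 1, mod, "pleasure")
    x <- sweep(r@data, 1, rowMeans(r@data))
    tcrossprod(x) / (ncol(x) - 1)
  }
  cfg <- tinyGenConfig(shift_strength = 0, sensor_noise = 0,
                       subject_jitter = 0, trial_s = 80, pre_s = 0,
                       active_bands = 6L)
  dNoShift <- relFrob(covOf(cfg, "audio"), covOf(cfg, "visual"))
  cfgS <- tinyGenConfig(shift_strength = 2, sensor_noise = 0,
                        subject_jitter = 0, trial_s = 80, pre_s = 0,
                        active_bands = 6L)
  dShift <- relFrob(covOf(cfgS, "audio"), covOf(cfgS, "visual"))
  expect_lt(dNoShift, 0.2)      # sampling noise only
  expect_gt(dShift, 2 * dNoShift)
})

test_that("the dataset grid and recordings realize the acquisition design", {
  cfg <- tinyGenConfig(n_subjects = 1L, n_trials = 1L)
  recs <- simulateDataset(cfg)
  expect_length(recs, 6L)       # 3 modalities x 2 emotions
  expect_identical(nrow(datasetGrid(generatorConfig())), 1200L)
  r <- recs[[1]]
  expect_identical(dim(r@data),
                   c(5L, as.integer((cfg$pre_s + cfg$trial_s) * cfg$fs)))
  expect_identical(r@onsetIndex, as.integer(cfg$pre_s * cfg$fs + 1))
  # determinism: same seed, bit-identical data
  recs2 <- simulateDataset(cfg)
  expect_identical(lapply(recs, function(x) x@data),
                   lapply(recs2, function(x) x@data))
  # a different seed changes the data
  recs3 <- simulateDataset(tinyGenConfig(n_subjects = 1L, n_trials = 1L,
                                         seed = 99L))
  expect_false(identical(recs[[1]]@data, recs3[[1]]@data))
})

test_that("a default-geometry trial has 31 x 15500 samples", {
  cfg <- generatorConfig(n_channels = 31L, seed = 5L)
  r <- simulateTrial(cfg, 1, "audio", "pleasure")
  expect_identical(dim(r@data), c(31L, 15500L))
})

test_that("injected noise realizes the requested signal-to-noise ratio", {
  set.seed(10)
  x <- rnorm(2000)
  x <- x / sqrt(mean(x^2))      # unit power
  # variance of the injected noise follows 10^(-snr/10)
  for (snr in c(0, 10)) {
    set.seed(1)
    y <- injectNoise(x, snr)
    noise <- y - x
    expect_equal(var(noise), 10^(-snr / 10), tolerance = 0.1)
  }
  # Monte-Carlo realized SNR within 0.1 dB at 1e6 samples
  set.seed(2)
  big <- rnorm(1e6, sd = 3)
  z <- injectNoise(big, 30)
  expect_lt(abs(attr(z, "realized_snr_db") - 30), 0.1)
  realized <- 10 * log10(mean(big^2) / mean((z - big)^2))
  expect_lt(abs(realized - 30), 0.1)
  expect_error(injectNoise(numeric(5) , 10), "zero-power")
})
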