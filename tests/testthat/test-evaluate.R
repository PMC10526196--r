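test_that("stratified folds realize the 60/20/20 split and partition the data", {
  labels <- rep(c("pleasure", "unpleasure"), each = 180)
  folds <- makeFolds(labels, 5L, seed = 3L)
  expect_length(folds, 5L)
  for (f in folds) {
    expect_length(f$test, 72L)
    expect_length(f$val, 72L)
    expect_length(f$train, 216L)
    expect_length(intersect(f$test, f$val), 0L)
    expect_length(intersect(f$test, f$train), 0L)
    # stratification: both classes balanced in every subset
    expect_equal(sum(labels[f$test] == "pleasure"), 36L)
  }
  # every sample serves as test exactly once
  expect_identical(sort(unlist(lapply(folds, `[[`, "test"))), 1:360)
  expect_identical(makeFolds(labels, 5L, seed = 3L), folds)
  expect_false(identical(makeFolds(labels, 5L, seed = 4L), folds))
  # remainders are dealt round-robin: sizes differ by at most one per class
  folds2 <- makeFolds(rep(c("pleasure", "unpleasure"), each = 13), 5L, 1L)
  sz <- vapply(folds2, function(f) length(f$test), numeric(1))
  expect_lte(max(sz) - min(sz), 2)
  expect_identical(sort(unlist(lapply(folds2, `[[`, "test"))), 1:26)
  expect_error(makeFolds(rep(c("pleasure", "unpleasure"), c(4, 30)), 5L, 1L),
               "at least 5")
})

test_that("variant nesting: the full method with adaptation disabled equals FBR", {
  cfg <- tinyGenConfig(n_subjects = 1L, n_trials = 5L, trial_s = 10,
                       n_channels = 4L)
  es <- bindEpochSets(lapply(simulateDataset(cfg), preprocessRecording))
  p1 <- protocolConfig(target_modality = "audio", variant = "FBR", seed = 2L)
  p2 <- protocolConfig(target_modality = "audio", variant = "FBADR",
                       adapt = FALSE, seed = 2L)
  r1 <- runVariant(es, p1)
  r2 <- runVariant(es, p2)
  expect_identical(r1$accuracy, r2$accuracy)
  # report aggregates are recomputable from the per-fold entries
  expect_equal(attr(r1, "mean_accuracy"), mean(r1$accuracy))
  s <- summarizeReport(r1)
  expect_equal(s$mean_accuracy, mean(r1$accuracy))
  # reruns under the same seed are bit-identical
  expect_identical(r1, runVariant(es, p1))
  # a different target modality runs cleanly (tiny adaptation budget)
  pv <- protocolConfig(variant = "FBADR", target_modality = "visual",
                       adapt_config = adaptTrainConfig(epochs = 1L, batch = 8L),
                       adaptor_args = list(conv_filters = c(2L, 2L),
                                           kernel = 2L),
                       critic_args = list(dense1 = 4L,
                                          conv_filters = c(2L, 2L),
                                          fc = c(4L, 2L)),
                       seed = 1L)
  expect_error(runVariant(es, pv), NA)
})

test_that("an easy regime without domain shift is decoded nearly perfectly", {
  cfg <- tinyGenConfig(n_subjects = 1L, n_trials = 5L, trial_s = 20,
                       n_channels = 5L, class_sep = 3, shift_strength = 0,
                       sensor_noise = 0.1)
  es <- bindEpochSets(lapply(simulateDataset(cfg), preprocessRecording))
  rep <- runVariant(es, protocolConfig(target_modality = "audio",
                                       variant = "FBR", seed = 4L))
  expect_gte(attr(rep, "mean_accuracy"), 0.95)
})

test_that("the robustness sweep records realized SNR and a clean baseline", {
  cfg <- tinyGenConfig(n_subjects = 1L, n_trials = 5L, trial_s = 10,
                       n_channels = 4L, class_sep = 3, shift_strength = 0,
                       sensor_noise = 0.1)
  es <- bindEpochSets(lapply(simulateDataset(cfg), preprocessRecording))
  prot <- protocolConfig(target_modality = "audio", variant = "RIE", seed = 6L)
  sw <- robustnessSweep(es, snr_levels = c(20, -5), protocol = prot)
  expect_setequal(unique(sw$snr), c(Inf, 20, -5))
  rs <- attr(sw, "realized_snr")
  expect_lt(abs(rs[["20"]] - 20), 0.1)
  expect_lt(abs(rs[["-5"]] - (-5)), 0.1)
  # the clean level equals a plain run of the same protocol
  base <- runVariant(es, prot)
  expect_identical(sw$accuracy[sw$snr == Inf], base$accuracy)
})
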