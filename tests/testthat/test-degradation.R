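test_that("attenuation is multiplicative, validated, and recorded", {
  s <- short_session()
  same <- attenuate(s$emg, 1)
  expect_identical(same$samples, s$emg$samples)
  twice <- attenuate(attenuate(s$emg, 0.5), 0.5)
  once <- attenuate(s$emg, 0.25)
  expect_equal(twice$samples, once$samples, tolerance = 1e-15)
  expect_equal(attr(twice, "attenuation"), 0.25)
  expect_error(attenuate(s$emg, 0), "fraction")
  expect_error(attenuate(s$emg, 1.2), "fraction")
})

test_that("attenuation propagates through the feature pipeline exactly", {
  s <- short_session()
  base <- short_emg_features()$features
  att <- emg_window_features(attenuate(s$emg, 0.3))$features
  expect_lt(max(abs(att - 0.3 * base)) / max(abs(0.3 * base)), 1e-9)
})

test_that("noise injection hits the closed-form sigma and the target SNR", {
  fs <- 1000
  n <- 1e6
  t <- (1:n) / fs
  unit_power <- multichannel_signal(matrix(sqrt(2) * sin(2 * pi * 7 * t)),
                                    fs, "s1")
  # 0 dB on a unit-power signal: sigma = 1
  noisy0 <- add_noise_at_snr(unit_power, 0, seed = 4)
  sigma0 <- sd(noisy0$samples - unit_power$samples)
  expect_equal(sigma0, 1, tolerance = 0.005)
  # 10 dB: sigma = sqrt(0.1)
  noisy10 <- add_noise_at_snr(unit_power, 10, seed = 4)
  sigma10 <- sd(noisy10$samples - unit_power$samples)
  expect_equal(sigma10, sqrt(0.1), tolerance = 0.005)
  # empirical SNR within +-0.05 dB
  p_sig <- mean(unit_power$samples^2)
  p_noise <- mean((noisy10$samples - unit_power$samples)^2)
  expect_lt(abs(10 * log10(p_sig / p_noise) - 10), 0.05)
})

test_that("noise injection preserves metadata and rejects dead channels", {
  s <- short_session()
  noisy <- add_noise_at_snr(s$emg, 3, seed = 9)
  expect_identical(dim(noisy$samples), dim(s$emg$samples))
  expect_identical(noisy$channel_labels, s$emg$channel_labels)
  expect_identical(noisy$sampling_rate, s$emg$sampling_rate)
  dead <- multichannel_signal(cbind(a = rnorm(100), b = 0), 1000)
  expect_error(add_noise_at_snr(dead, 3, seed = 1), "zero-power")
})

test_that("the temporary regime never touches the training split", {
  s <- short_session()
  splits <- split_session(s)
  emg_splits <- lapply(splits, `[[`, "emg")
  for (f in c(0.9, 0.5, 0.1)) {
    out <- apply_experiment(emg_splits, temporary_alteration(f))
    expect_identical(out$train$samples, emg_splits$train$samples)
    expect_equal(out$test$samples, emg_splits$test$samples * f,
                 tolerance = 1e-15)
    expect_equal(out$validation$samples, emg_splits$validation$samples * f,
                 tolerance = 1e-15)
  }
  # no attenuation: everything bit-identical
  clean <- apply_experiment(emg_splits, temporary_alteration(1))
  expect_identical(clean$test$samples, emg_splits$test$samples)
  # the +-10 percentage-point robustness protocol decouples the fractions
  mix <- apply_experiment(emg_splits,
                          temporary_alteration(0.4,
                                               validation_fraction = 0.5))
  expect_equal(mix$validation$samples, emg_splits$validation$samples * 0.5,
               tolerance = 1e-15)
  expect_equal(mix$test$samples, emg_splits$test$samples * 0.4,
               tolerance = 1e-15)
})

test_that("the permanent regime subsets, attenuates and degrades all splits", {
  s <- short_session()
  splits <- split_session(s)
  emg_splits <- lapply(splits, `[[`, "emg")
  regime <- permanent_alteration(target_snr_db = 10, noise_seed = 2)
  out <- apply_experiment(emg_splits, regime)
  for (nm in c("train", "validation", "test")) {
    expect_identical(colnames(out[[nm]]$samples), c("VM_R", "VM_L"))
    expect_identical(ncol(out[[nm]]$samples), 2L)
    expect_identical(nrow(out[[nm]]$samples), nrow(emg_splits[[nm]]$samples))
  }
  # attenuation applied before noise: subtracting the noise leaves 0.3x
  no_noise <- apply_experiment(emg_splits,
                               permanent_alteration(target_snr_db = NA))
  resid <- out$train$samples - no_noise$train$samples
  p_sig <- colMeans(no_noise$train$samples^2)
  snr_db <- 10 * log10(p_sig / colMeans(resid^2))
  expect_true(all(abs(snr_db - 10) < 0.2))
  expect_equal(no_noise$train$samples,
               emg_splits$train$samples[, c("VM_R", "VM_L")] * 0.3,
               tolerance = 1e-15, ignore_attr = TRUE)
  expect_error(apply_experiment(emg_splits, list()), "regime")
})
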