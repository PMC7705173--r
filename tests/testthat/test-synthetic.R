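test_that("square-wave gait yields the closed-form label fractions", {
  fw <- ideal_footswitch()
  tab <- table(fw$labels$labels) / length(fw$labels)
  # stance_fraction 0.6, offset 0.5, 1 s cycles: per cycle the right leg
  # swings 0.4 s, the left 0.4 s, and double support covers 2 x 0.1 s
  expect_equal(unname(tab[["RIGHT"]]), 0.40, tolerance = 1e-12)
  expect_equal(unname(tab[["LEFT"]]), 0.40, tolerance = 1e-12)
  expect_equal(unname(tab[["STANCE"]]), 0.20, tolerance = 1e-12)
})

test_that("foot contact defines the labels and conserves every sample", {
  fw <- ideal_footswitch()
  s <- fw$footswitch$samples
  contact_r <- s[, "heel_R"] | s[, "toe_R"]
  contact_l <- s[, "heel_L"] | s[, "toe_L"]
  lab <- fw$labels$labels
  expect_true(all(lab[!contact_r] == "RIGHT"))
  expect_true(all(lab[!contact_l] == "LEFT"))
  expect_true(all(lab[contact_r & contact_l] == "STANCE"))
  # walking, not running: both feet are never off the ground
  expect_true(all(contact_r | contact_l))
  expect_equal(sum(table(lab)), length(lab))
})

test_that("jitter-free labels are exactly periodic with the cycle length", {
  fw <- ideal_footswitch()
  lab <- fw$labels$labels
  period <- 1000L  # 1 s cycle at 1 kHz
  expect_identical(lab[1:(length(lab) - period)],
                   lab[(period + 1):length(lab)])
})

test_that("high stance fraction makes double support dominate", {
  p <- gait_cycle_params(cycle_duration = 1, jitter_sd = 0,
                         stance_fraction = 0.79, duration = 10,
                         sampling_rate = 1000)
  fw <- simulate_footswitch(p, seed = 1)
  tab <- table(fw$labels$labels) / length(fw$labels)
  # stance occupies 2 * 0.79 - 1 of the cycle
  expect_equal(unname(tab[["STANCE"]]), 0.58, tolerance = 1e-12)
  expect_gt(tab[["STANCE"]], tab[["RIGHT"]])
})

test_that("overlapping swing phases are rejected as invalid walking", {
  expect_error(gait_cycle_params(stance_fraction = 0.55,
                                 leg_phase_offset = 0.1),
               "simultaneous flight")
  expect_error(gait_cycle_params(jitter_sd = 0.5), "jitter")
})

test_that("generators are bit-identical under a repeated seed", {
  p <- gait_cycle_params(duration = 5)
  a <- simulate_session(p, seed = 33)
  b <- simulate_session(p, seed = 33)
  expect_identical(a$footswitch$samples, b$footswitch$samples)
  expect_identical(a$labels$labels, b$labels$labels)
  expect_identical(a$emg$samples, b$emg$samples)
  expect_identical(a$eeg$samples, b$eeg$samples)
  c <- simulate_session(p, seed = 34)
  expect_false(identical(a$emg$samples, c$emg$samples))
})

test_that("zero burst gain leaves pure baseline noise", {
  fw <- ideal_footswitch()
  quiet <- lapply(default_muscle_models(), function(m) {
    m$burst_gain <- 0
    m
  })
  emg <- simulate_emg(fw$labels, quiet, seed = 2)
  sds <- apply(emg$samples, 2, sd)
  expect_true(all(abs(sds - 8) / 8 < 0.1))   # baseline_noise_sd = 8 uV
})

test_that("swing-phase muscles are louder in their leg's swing windows", {
  s <- short_session()
  feats <- short_emg_features()
  lab <- feats$labels
  # TA fires in swing: rectified amplitude higher in that leg's swing
  expect_gt(mean(feats$features[lab == "RIGHT", "TA_R"]),
            mean(feats$features[lab == "STANCE", "TA_R"]))
  expect_gt(mean(feats$features[lab == "LEFT", "TA_L"]),
            mean(feats$features[lab == "STANCE", "TA_L"]))
  # VM fires in early stance, not in its own swing
  expect_gt(mean(feats$features[lab == "STANCE", "VM_R"]),
            mean(feats$features[lab == "RIGHT", "VM_R"]))
})

test_that("EMG carrier bands beyond Nyquist are rejected", {
  fw <- ideal_footswitch()
  bad <- muscle_model("TA", "right", activation_centers = 0.8,
                      activation_widths = 0.1, carrier_band = c(20, 600))
  expect_error(simulate_emg(fw$labels, list(bad), seed = 1), "Nyquist")
})

test_that("zero cortical contrast makes EEG band power label-independent", {
  p <- gait_cycle_params(cycle_duration = 1, jitter_sd = 0,
                         stance_fraction = 0.6, duration = 40,
                         sampling_rate = 1000)
  fw <- simulate_footswitch(p, seed = 8)
  cm <- cortical_model(modulation_contrast = 0)
  eeg <- simulate_eeg(fw$labels, cm, seed = 9)
  bp <- zerophase_filter(eeg$samples[, 8], 4, c(1, 8), 1000, "pass")
  sw <- fw$labels$labels != "STANCE"
  ratio <- mean(bp[sw]^2) / mean(bp[!sw]^2)
  expect_lt(abs(log(ratio)), log(1.25))
})

test_that("strong contrast raises swing-phase band power in nearly every cycle", {
  p <- gait_cycle_params(duration = 60, sampling_rate = 1000)
  fw <- simulate_footswitch(p, seed = 11)
  cm <- cortical_model(background_sd = 0.5, modulation_contrast = 3)
  eeg <- simulate_eeg(fw$labels, cm, seed = 12)
  bp <- zerophase_filter(eeg$samples[, 8], 4, c(1, 8), 1000, "pass")
  sw <- fw$labels$labels != "STANCE"
  cyc <- cumsum(c(TRUE, diff(fw$labels$phase_right) < -0.5))
  per_cycle <- vapply(split(seq_along(bp), cyc), function(i) {
    s <- i[sw[i]]; t <- i[!sw[i]]
    if (!length(s) || !length(t)) return(NA)
    mean(bp[s]^2) > mean(bp[t]^2)
  }, logical(1))
  expect_gte(mean(per_cycle, na.rm = TRUE), 0.95)
})

test_that("channels without locking gain carry no label information", {
  p <- gait_cycle_params(duration = 60, sampling_rate = 1000)
  fw <- simulate_footswitch(p, seed = 21)
  gains <- rep(0, 8); gains[7] <- 15
  cm <- cortical_model(n_channels = 8, locking_gain = gains,
                       background_sd = 4, modulation_contrast = 2)
  eeg <- simulate_eeg(fw$labels, cm, seed = 22)
  sw <- fw$labels$labels != "STANCE"
  # class contrast in band power, channel by channel, against a
  # permutation null built from circularly shifted labels
  contrast_of <- function(x, swing) {
    bp <- zerophase_filter(x, 4, c(1, 8), 1000, "pass")
    abs(log(mean(bp[swing]^2) / mean(bp[!swing]^2)))
  }
  shifts <- round(seq(5000, 55000, length.out = 20))
  for (ch in seq_len(8)) {
    obs <- contrast_of(eeg$samples[, ch], sw)
    null <- vapply(shifts, function(s) {
      contrast_of(eeg$samples[, ch], c(sw[-(1:s)], sw[1:s]))
    }, numeric(1))
    exceed <- mean(null >= obs)
    if (ch == 7) {
      expect_lt(exceed, 0.05)   # locked channel: far outside the null
    } else {
      expect_gt(exceed, 0.05)   # unlocked channels: within the null
    }
  }
})

test_that("sessions survive a round trip through the CSV container", {
  p <- gait_cycle_params(duration = 2)
  ses <- simulate_session(p, seed = 3)
  dir <- tempfile("session")
  write_session(ses, dir)
  back <- read_session(dir)
  expect_equal(back$eeg$samples, ses$eeg$samples, ignore_attr = TRUE)
  expect_equal(back$emg$samples, ses$emg$samples, ignore_attr = TRUE)
  expect_identical(back$labels$labels, ses$labels$labels)
  expect_equal(back$labels$phase_right, ses$labels$phase_right)
  expect_equal(back$seed, ses$seed)
  unlink(dir, recursive = TRUE)
})
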