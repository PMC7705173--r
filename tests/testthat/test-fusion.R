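test_that("confusion counts follow the (true, predicted) definition", {
  cls <- c("RIGHT", "LEFT", "STANCE")
  cm <- estimate_confusion(c("RIGHT", "RIGHT", "LEFT", "STANCE"),
                           c("RIGHT", "LEFT", "LEFT", "STANCE"), cls)
  expect_identical(cm["RIGHT", "RIGHT"], 1L)
  expect_identical(cm["RIGHT", "LEFT"], 1L)
  expect_identical(cm["LEFT", "LEFT"], 1L)
  expect_identical(cm["STANCE", "STANCE"], 1L)
  expect_identical(sum(cm), 4L)
  # perfect predictions give a diagonal matrix
  perfect <- estimate_confusion(cls, cls, cls)
  expect_identical(unname(diag(unclass(perfect))), rep(1L, 3))
  expect_identical(sum(perfect) - sum(diag(unclass(perfect))), 0L)
  expect_error(estimate_confusion("RIGHT", "UP", cls), "unknown")
  expect_error(estimate_confusion(c("RIGHT", "LEFT"), "RIGHT", cls),
               "length")
})

test_that("column normalization and smoothing behave as specified", {
  cls <- c("RIGHT", "LEFT", "STANCE")
  ident <- estimate_confusion(cls, cls, cls)
  expect_equal(unname(conditionals_from_confusion(ident, alpha = 0)),
               diag(3))
  cm <- matrix(c(8, 1, 1, 0, 9, 1, 2, 0, 8), 3, 3,
               dimnames = list(cls, cls))
  cond <- conditionals_from_confusion(cm, alpha = 0)
  expect_equal(unname(cond[, 1]), c(0.8, 0.1, 0.1))
  expect_equal(colSums(cond), c(RIGHT = 1, LEFT = 1, STANCE = 1))
  # an all-zero column is undefined raw but uniform under smoothing
  cm0 <- matrix(c(5, 0, 0, 0, 5, 0, 0, 0, 0), 3, 3,
                dimnames = list(cls, cls))
  expect_error(conditionals_from_confusion(cm0, alpha = 0), "undefined")
  sm <- conditionals_from_confusion(cm0, alpha = 1)
  expect_equal(unname(sm[, 3]), rep(1 / 3, 3))
})

test_that("fused beliefs reproduce the hand-computed reference case", {
  eeg_cond <- matrix(c(0.9, 0.1, 0.4, 0.6), 2, 2)
  emg_cond <- matrix(c(0.7, 0.2, 0.1, 0.1, 0.8, 0.1, 0.1, 0.1, 0.8), 3, 3)
  fm <- fusion_model(eeg_cond, emg_cond)
  fz <- fuse("SWING", "RIGHT", fm)
  expect_equal(unname(fz$belief),
               c(0.9 * 0.7, 0.9 * 0.2, 0.1 * 0.1) / 3, tolerance = 1e-12)
  expect_identical(fz$decision, "RIGHT")
})

test_that("perfect conditionals make fusion follow the agreeing decoders", {
  fm <- fusion_model(diag(2), diag(3))
  fz <- fuse("STANCE", "STANCE", fm)
  expect_equal(unname(fz$belief), c(0, 0, 1 / 3))
  expect_identical(fz$decision, "STANCE")
  # EMG identical to ground truth with identity conditionals dominates
  truth <- sample(c("RIGHT", "LEFT", "STANCE"), 200, TRUE)
  eeg_pred <- sample(c("SWING", "STANCE"), 200, TRUE)
  fm2 <- fusion_model(matrix(c(0.7, 0.3, 0.3, 0.7), 2), diag(3))
  out <- fuse_sequence(eeg_pred, truth, fm2)
  expect_identical(out$decision, truth)
})

test_that("uninformative EMG leaves a right/left tie broken by preference", {
  emg_flat <- matrix(1 / 3, 3, 3)
  fm <- fusion_model(matrix(c(0.95, 0.05, 0.2, 0.8), 2), emg_flat)
  fz <- fuse("SWING", "STANCE", fm)
  expect_equal(fz$belief[["RIGHT"]], fz$belief[["LEFT"]])
  expect_gt(fz$belief[["RIGHT"]], fz$belief[["STANCE"]])
  # deterministic preference STANCE > RIGHT > LEFT among tied maxima
  expect_identical(fz$decision, "RIGHT")
  # full three-way tie resolves to STANCE
  fm3 <- fusion_model(matrix(0.5, 2, 2), emg_flat)
  expect_identical(fuse("SWING", "RIGHT", fm3)$decision, "STANCE")
})

test_that("fuse matches a brute-force belief evaluation over random tables", {
  # independent oracle: literal product over the two classifiers with the
  # repeated-SWING class mapping, written against the formula rather
  # than the implementation
  oracle <- function(e_eeg, e_emg, eeg_cond, emg_cond, priors) {
    eeg_classes <- c("SWING", "STANCE")
    fused <- c("RIGHT", "LEFT", "STANCE")
    map_eeg <- c(RIGHT = "SWING", LEFT = "SWING", STANCE = "STANCE")
    bel <- numeric(3)
    for (i in 1:3) {
      p_eeg <- eeg_cond[match(map_eeg[[fused[i]]], eeg_classes),
                        match(e_eeg, eeg_classes)]
      p_emg <- emg_cond[match(fused[i], fused), match(e_emg, fused)]
      bel[i] <- p_eeg * p_emg * priors[i]
    }
    bel
  }
  set.seed(42)
  worst <- 0
  for (rep in 1:1000) {
    eeg_cond <- random_conditionals(2)
    emg_cond <- random_conditionals(3)
    fm <- fusion_model(eeg_cond, emg_cond)
    for (e_eeg in c("SWING", "STANCE")) {
      for (e_emg in c("RIGHT", "LEFT", "STANCE")) {
        got <- fuse(e_eeg, e_emg, fm)$belief
        want <- oracle(e_eeg, e_emg, eeg_cond, emg_cond, rep(1, 3) / 3)
        worst <- max(worst, max(abs(got - want) / pmax(abs(want), 1e-300)))
      }
    }
  }
  expect_lt(worst, 1e-12)
})

test_that("belief ratios between right and left never involve the EEG", {
  set.seed(7)
  for (rep in 1:50) {
    fm <- fusion_model(random_conditionals(2), random_conditionals(3))
    for (e_emg in c("RIGHT", "LEFT", "STANCE")) {
      r1 <- fuse("SWING", e_emg, fm)$belief
      r2 <- fuse("STANCE", e_emg, fm)$belief
      expect_equal(r1[["RIGHT"]] / r1[["LEFT"]],
                   r2[["RIGHT"]] / r2[["LEFT"]], tolerance = 1e-12)
    }
  }
})

test_that("relabeling right and left everywhere swaps the fused output", {
  set.seed(13)
  emg_cond <- random_conditionals(3)
  fm <- fusion_model(random_conditionals(2), emg_cond)
  swap <- c(RIGHT = "LEFT", LEFT = "RIGHT", STANCE = "STANCE")
  emg_sw <- emg_cond[c(2, 1, 3), c(2, 1, 3)]
  fm_sw <- fusion_model(fm$eeg, emg_sw)
  eeg_pred <- sample(c("SWING", "STANCE"), 300, TRUE)
  emg_pred <- sample(c("RIGHT", "LEFT", "STANCE"), 300, TRUE)
  out <- fuse_sequence(eeg_pred, emg_pred, fm)
  out_sw <- fuse_sequence(eeg_pred, unname(swap[emg_pred]), fm_sw)
  # ties break asymmetrically (STANCE > RIGHT > LEFT), so compare only
  # windows with a strict belief maximum
  strict <- apply(out$belief, 1, function(b) sum(b == max(b)) == 1)
  expect_identical(out_sw$decision[strict],
                   unname(swap[out$decision[strict]]))
})

test_that("the two prior weightings agree under uniform priors", {
  set.seed(3)
  fm_p <- fusion_model(random_conditionals(2), random_conditionals(3),
                       form = "product")
  fm_n <- fusion_model(fm_p$eeg, fm_p$emg, form = "normalized")
  for (e_eeg in c("SWING", "STANCE")) {
    for (e_emg in c("RIGHT", "LEFT", "STANCE")) {
      a <- fuse(e_eeg, e_emg, fm_p)
      b <- fuse(e_eeg, e_emg, fm_n)
      expect_identical(a$decision, b$decision)
      # beliefs differ only by the constant 1/prior^2 rescaling
      expect_equal(b$belief / a$belief, rep(9, 3), tolerance = 1e-12,
                   ignore_attr = TRUE)
    }
  }
})

test_that("sequence fusion validates alignment and stays constant on constants", {
  fm <- fusion_model(diag(2), diag(3))
  expect_error(fuse_sequence(c("SWING", "SWING"), "STANCE", fm), "length")
  out <- fuse_sequence(rep("STANCE", 10), rep("STANCE", 10), fm)
  expect_identical(unique(out$decision), "STANCE")
  expect_error(fuse("UP", "STANCE", fm), "unknown")
  expect_error(fuse_sequence("SWING", "STANCE", list()), "calibrated")
})

test_that("fusion models survive a JSON round trip", {
  set.seed(77)
  fm <- fusion_model(random_conditionals(2), random_conditionals(3),
                     alpha = 1)
  path <- tempfile(fileext = ".json")
  write_fusion_model(fm, path)
  back <- read_fusion_model(path)
  expect_equal(unclass(back$eeg), unclass(fm$eeg), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(back$emg), unclass(fm$emg), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$priors, fm$priors)
  for (e_eeg in c("SWING", "STANCE")) {
    for (e_emg in c("RIGHT", "LEFT", "STANCE")) {
      expect_identical(fuse(e_eeg, e_emg, back)$decision,
                       fuse(e_eeg, e_emg, fm)$decision)
    }
  }
  unlink(path)
})

test_that("calibration estimates conditionals from labelled predictions", {
  set.seed(5)
  truth <- sample(c("RIGHT", "LEFT", "STANCE"), 400, TRUE)
  emg_pred <- ifelse(runif(400) < 0.9, truth,
                     sample(c("RIGHT", "LEFT", "STANCE"), 400, TRUE))
  eeg_pred <- ifelse(runif(400) < 0.8, to_eeg_classes(truth),
                     sample(c("SWING", "STANCE"), 400, TRUE))
  fm <- calibrate_fusion(truth, eeg_pred, truth, emg_pred, alpha = 1)
  cms <- attr(fm, "confusions")
  expect_identical(sum(cms$eeg), 400L)
  expect_identical(sum(cms$emg), 400L)
  expect_equal(colSums(fm$eeg), c(SWING = 1, STANCE = 1))
  expect_equal(colSums(fm$emg), c(RIGHT = 1, LEFT = 1, STANCE = 1))
  # reliable decoders produce diagonally dominant conditionals
  expect_gt(fm$emg["RIGHT", "RIGHT"], 0.5)
  expect_gt(fm$eeg["SWING", "SWING"], 0.5)
})
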