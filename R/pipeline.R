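#' Split a session into contiguous train / validation / test segments
#'
#' Splits are contiguous and time-ordered (train, then validation, then
#' test), emulating online usage where the test stream follows
#' calibration; shuffled splits would leak gait-cycle context through
#' overlapping windows. Features are extracted per split, so analysis
#' windows never straddle a split boundary.
#'
#' @param session A `gait_session` from [simulate_session()].
#' @param fractions Length-3 split fractions summing to 1 (default
#'   `c(0.60, 0.15, 0.25)`).
#' @return Named list `train`, `validation`, `test`; each element has
#'   `eeg`, `emg`, `footswitch`, `labels` over its sample range.
#' @export
split_session <- function(session, fractions = c(0.60, 0.15, 0.25)) {
  stopifnot(inherits(session, "gait_session"), length(fractions) == 3,
            all(fractions >= 0), abs(sum(fractions) - 1) < 1e-9)
  n <- length(session$labels)
  n_train <- as.integer(floor(fractions[1] * n))
  n_val <- as.integer(floor(fractions[2] * n))
  bounds <- list(train = c(1L, n_train),
                 validation = c(n_train + 1L, n_train + n_val),
                 test = c(n_train + n_val + 1L, n))
  out <- lapply(bounds, function(b) {
    if (b[1] > b[2]) {
      return(list(eeg = NULL, emg = NULL, footswitch = NULL, labels = NULL,
                  range = b))
    }
    list(eeg = signal_slice(session$eeg, b[1], b[2]),
         emg = signal_slice(session$emg, b[1], b[2]),
         footswitch = signal_slice(session$footswitch, b[1], b[2]),
         labels = labels_slice(session$labels, b[1], b[2]),
         range = b)
  })
  out
}

#' Experiment configuration
#'
#' One config drives a full reproducible run: simulate a session, split
#' it 60/15/25, extract features, train the two decoders, calibrate the
#' fusion on the validation split, retrain on train+validation, degrade
#' the EMG according to the chosen regime, decode the test stream, and
#' score EMG-only, EEG-only and fused decisions per condition.
#'
#' @param gait A [gait_cycle_params()].
#' @param cortical A [cortical_model()].
#' @param muscles List of [muscle_model()]s.
#' @param window A [window_spec()].
#' @param fractions Split fractions (default `c(0.60, 0.15, 0.25)`).
#' @param temporary_levels Retained-amplitude fractions for the
#'   temporary-impairment sweep (default `c(1, 0.9, 0.5, 0.3, 0.1)`).
#' @param permanent_snr_db Target SNRs in dB for the
#'   permanent-impairment sweep (default
#'   `c(10, 3, 1.5, 1, 0.5, 0.1)`); a no-noise baseline condition is
#'   always included.
#' @param alpha Fusion smoothing (default 1).
#' @param max_epochs,learning_rate,batch_size,seq_len,patience Training
#'   hyperparameters shared by both decoders.
#' @param emg_max_epochs Training epochs for the EMG decoder (defaults
#'   to `max_epochs`; the small EMG network converges in fewer epochs
#'   than the EEG one).
#' @param retrain_epochs Epochs of the warm-started retraining on
#'   train+validation after fusion calibration (default 2): a brief
#'   continuation incorporates the validation data while keeping the
#'   network behaviorally close to the one the fusion was calibrated
#'   on.
#' @param stateful Stateful decoding of validation/test streams
#'   (default `TRUE`).
#' @param seed Global seed; one seed corresponds to one synthetic
#'   subject.
#' @return A `run_config` object.
#' @export
run_config <- function(gait = gait_cycle_params(),
                       cortical = cortical_model(),
                       muscles = default_muscle_models(
                         stance_fraction = gait$stance_fraction),
                       window = window_spec(),
                       fractions = c(0.60, 0.15, 0.25),
                       temporary_levels = c(1, 0.9, 0.5, 0.3, 0.1),
                       permanent_snr_db = c(10, 3, 1.5, 1, 0.5, 0.1),
                       alpha = 1, max_epochs = 12, learning_rate = 2e-3,
                       batch_size = 16, seq_len = 100, patience = 10,
                       retrain_epochs = 2, emg_max_epochs = max_epochs,
                       stateful = TRUE, seed = 1L) {
  structure(list(gait = gait, cortical = cortical, muscles = muscles,
                 window = window, fractions = fractions,
                 temporary_levels = temporary_levels,
                 permanent_snr_db = permanent_snr_db, alpha = alpha,
                 max_epochs = max_epochs, learning_rate = learning_rate,
                 batch_size = batch_size, seq_len = seq_len,
                 patience = patience, retrain_epochs = retrain_epochs,
                 emg_max_epochs = emg_max_epochs, stateful = stateful,
                 seed = as.integer(seed)),
            class = "run_config")
}

# Train the stage-1 decoder (training split, validation early stopping)
# and the stage-2 decoder retrained on train+validation, warm-started
# from stage 1 so the fusion calibration transfers to the network that
# decodes the test stream.
train_pair <- function(spec, tr_feat, va_feat, retrain_epochs = NULL) {
  stage1 <- train_decoder(tr_feat, spec = spec,
                          validation = list(features = va_feat))
  spec2 <- spec
  if (!is.null(retrain_epochs)) {
    spec2$max_epochs <- as.integer(retrain_epochs)
    spec2$patience <- as.integer(retrain_epochs)
  }
  stage2 <- retrain_on_train_plus_validation(spec2, tr_feat,
                                             val_features = va_feat,
                                             init = stage1)
  list(stage1 = stage1, stage2 = stage2)
}

emg_split_features <- function(emg_splits, splits, window) {
  lapply(names(emg_splits), function(nm) {
    emg_window_features(emg_splits[[nm]], window,
                        labels = splits[[nm]]$labels)
  }) |> stats::setNames(names(emg_splits))
}

# Calibrate on validation with stage-1 decoders, then score the test
# stream with stage-2 decoders and the fused stream.
run_condition <- function(eeg_pair, emg_pair, eeg_feats, emg_feats,
                          alpha, stateful) {
  eeg_val_pred <- predict(eeg_pair$stage1, eeg_feats$validation,
                          stateful = stateful)$class
  emg_val_pred <- predict(emg_pair$stage1, emg_feats$validation,
                          stateful = stateful)$class
  fm <- calibrate_fusion(eeg_feats$validation$labels, eeg_val_pred,
                         emg_feats$validation$labels, emg_val_pred,
                         alpha = alpha)
  eeg_test_pred <- predict(eeg_pair$stage2, eeg_feats$test,
                           stateful = stateful)$class
  emg_test_pred <- predict(emg_pair$stage2, emg_feats$test,
                           stateful = stateful)$class
  fused <- fuse_sequence(eeg_test_pred, emg_test_pred, fm)
  truth <- emg_feats$test$labels
  list(fusion_model = fm,
       predictions = list(eeg = eeg_test_pred, emg = emg_test_pred,
                          fused = fused$decision),
       reports = list(
         emg = score(truth, emg_test_pred, GAIT_CLASSES),
         eeg = score(to_eeg_classes(truth), eeg_test_pred, EEG_CLASSES),
         fused = score(truth, fused$decision, GAIT_CLASSES)))
}

#' Run a full degradation experiment
#'
#' Executes the end-to-end protocol for one synthetic subject under both
#' impairment regimes (or a chosen subset). The EEG stream is never
#' degraded, so the EEG decoder pair is trained once and shared across
#' conditions. In the temporary regime the EMG decoders are trained on
#' clean signals only and the attenuation touches the validation (for
#' fusion calibration) and test splits; in the permanent regime each
#' condition retrains the EMG decoders on the altered training split.
#' Identical config + seed give identical results.
#'
#' @param config A [run_config()].
#' @param regimes Character subset of `c("temporary", "permanent")`.
#' @param verbose Print progress messages.
#' @return A `run_bundle`: list with `session` metadata, `temporary` and
#'   `permanent` condition lists (each condition holding the fusion
#'   model, test predictions and three [score()] reports), and a long
#'   `comparison` table from [compare_conditions()].
#' @export
run_experiment <- function(config = run_config(),
                           regimes = c("temporary", "permanent"),
                           verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  regimes <- match.arg(regimes, several.ok = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  say("simulating session (seed %d)", config$seed)
  session <- simulate_session(config$gait, config$muscles, config$cortical,
                              seed = config$seed)
  splits <- split_session(session, config$fractions)
  g <- window_geometry(config$window, session$labels$sampling_rate)
  for (nm in names(splits)) {
    if (is.null(splits[[nm]]$labels) ||
        length(splits[[nm]]$labels) < g$w) {
      stop("split '", nm, "' is shorter than one analysis window")
    }
  }

  say("extracting EEG features")
  eeg_feats <- lapply(splits, function(s) {
    eeg_window_features(s$eeg, config$window, labels = s$labels)
  })
  clean_emg <- lapply(splits, `[[`, "emg")

  spec_args <- list(learning_rate = config$learning_rate,
                    batch_size = config$batch_size,
                    seq_len = config$seq_len,
                    max_epochs = config$max_epochs,
                    patience = config$patience,
                    seed = config$seed)
  eeg_spec <- do.call(eeg_network_spec,
                      c(list(ncol(session$eeg$samples)), spec_args))

  say("training EEG decoder (shared across conditions)")
  eeg_pair <- train_pair(eeg_spec, eeg_feats$train, eeg_feats$validation,
                         config$retrain_epochs)

  bundle <- list(session = list(seed = config$seed,
                                n_samples = length(session$labels),
                                sampling_rate = session$labels$sampling_rate,
                                decision_rate = g$decision_rate),
                 config = config)

  if ("temporary" %in% regimes) {
    say("temporary regime: training clean EMG decoder")
    emg_feats_clean <- emg_split_features(clean_emg, splits, config$window)
    emg_spec <- do.call(emg_network_spec,
                        c(list(ncol(session$emg$samples)), spec_args))
    emg_spec$max_epochs <- as.integer(config$emg_max_epochs)
    emg_pair <- train_pair(emg_spec, emg_feats_clean$train,
                           emg_feats_clean$validation,
                           config$retrain_epochs)
    conditions <- list()
    for (f in config$temporary_levels) {
      say("temporary regime: retained fraction %.2f", f)
      altered <- apply_experiment(clean_emg, temporary_alteration(f))
      stopifnot(identical(altered$train$samples, clean_emg$train$samples))
      emg_feats <- list(
        train = emg_feats_clean$train,
        validation = emg_window_features(altered$validation, config$window,
                                         labels = splits$validation$labels),
        test = emg_window_features(altered$test, config$window,
                                   labels = splits$test$labels))
      conditions[[sprintf("%.0f%%", 100 * f)]] <-
        run_condition(eeg_pair, emg_pair, eeg_feats, emg_feats,
                      config$alpha, config$stateful)
    }
    bundle$temporary <- conditions
  }

  if ("permanent" %in% regimes) {
    conditions <- list()
    snr_levels <- c(NA, config$permanent_snr_db)
    for (snr in snr_levels) {
      tag <- if (is.na(snr)) "no-noise" else sprintf("%gdB", snr)
      say("permanent regime: %s", tag)
      regime <- permanent_alteration(target_snr_db = snr,
                                     noise_seed = config$seed * 7L)
      altered <- apply_experiment(clean_emg, regime)
      emg_feats <- emg_split_features(altered, splits, config$window)
      emg_spec <- do.call(emg_network_spec,
                          c(list(length(regime$retained_channels)),
                            spec_args))
      emg_spec$max_epochs <- as.integer(config$emg_max_epochs)
      emg_pair <- train_pair(emg_spec, emg_feats$train,
                             emg_feats$validation,
                             config$retrain_epochs)
      conditions[[tag]] <-
        run_condition(eeg_pair, emg_pair, eeg_feats, emg_feats,
                      config$alpha, config$stateful)
    }
    bundle$permanent <- conditions
  }

  comp <- list()
  if (!is.null(bundle$temporary)) {
    comp$temporary <- compare_conditions(
      lapply(bundle$temporary, `[[`, "reports"), regime = "temporary")
  }
  if (!is.null(bundle$permanent)) {
    comp$permanent <- compare_conditions(
      lapply(bundle$permanent, `[[`, "reports"), regime = "permanent")
  }
  bundle$comparison <- do.call(rbind, comp)
  rownames(bundle$comparison) <- NULL
  class(bundle) <- "run_bundle"
  bundle
}

#' @export
print.run_bundle <- function(x, ...) {
  cat(sprintf("<run_bundle> seed %d, %d-sample session @ %g Hz\n",
              x$session$seed, x$session$n_samples, x$session$sampling_rate))
  for (regime in c("temporary", "permanent")) {
    if (is.null(x[[regime]])) next
    cat(sprintf("%s regime:\n", regime))
    for (lev in names(x[[regime]])) {
      r <- x[[regime]][[lev]]$reports
      cat(sprintf("  %-9s emg %.3f | eeg %.3f | fused %.3f\n", lev,
                  r$emg$accuracy, r$eeg$accuracy, r$fused$accuracy))
    }
  }
  invisible(x)
}
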