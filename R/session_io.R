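#' Persist a synthetic session as a directory of plain-text matrices
#'
#' Writes `eeg.csv`, `emg.csv`, `footswitch.csv` (one column per
#' channel), `labels.csv` (label plus per-leg cycle phase) and
#' `meta.json` (sampling rate, seed, gait parameters) under `dir`.
#'
#' @param session A `gait_session`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  stopifnot(inherits(session, "gait_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(m, f) {
    utils::write.csv(as.data.frame(m), file.path(dir, f), row.names = FALSE)
  }
  wr(session$eeg$samples, "eeg.csv")
  wr(session$emg$samples, "emg.csv")
  wr(session$footswitch$samples, "footswitch.csv")
  wr(data.frame(label = session$labels$labels,
                phase_right = session$labels$phase_right,
                phase_left = session$labels$phase_left), "labels.csv")
  gp <- session$params$gait
  meta <- list(sampling_rate = session$labels$sampling_rate,
               seed = session$seed,
               gait = gp[setdiff(names(gp), character(0))])
  jsonlite::write_json(meta, file.path(dir, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Directory containing the session files.
#' @return A `gait_session` (the `params` element holds only the gait
#'   parameters recorded in `meta.json`).
#' @export
read_session <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  fs <- meta$sampling_rate
  rd <- function(f) as.matrix(utils::read.csv(file.path(dir, f)))
  lab <- utils::read.csv(file.path(dir, "labels.csv"),
                         stringsAsFactors = FALSE)
  structure(list(
    eeg = multichannel_signal(rd("eeg.csv"), fs, units = "uV"),
    emg = multichannel_signal(rd("emg.csv"), fs, units = "uV"),
    footswitch = multichannel_signal(rd("footswitch.csv"), fs,
                                     units = "binary"),
    labels = gait_labels(lab$label, fs, phase_right = lab$phase_right,
                         phase_left = lab$phase_left),
    seed = meta$seed,
    params = list(gait = meta$gait)),
    class = "gait_session")
}

#' Write a feature sequence as CSV
#'
#' One row per window: window end time, per-channel features, and the
#' window label if present.
#'
#' @param fs A [feature_sequence()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(fs, path) {
  stopifnot(inherits(fs, "feature_sequence"))
  df <- data.frame(time = fs$window_end_times, fs$features,
                   check.names = FALSE)
  if (!is.null(fs$labels)) df$label <- fs$labels
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a fused decision stream as CSV
#'
#' Columns: window time, the two decoder predictions, the three class
#' beliefs, and the fused decision.
#'
#' @param times Window end times (seconds).
#' @param eeg_predictions,emg_predictions Per-window decoder predictions.
#' @param fused Result of [fuse_sequence()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_decision_stream <- function(times, eeg_predictions, emg_predictions,
                                  fused, path) {
  df <- data.frame(time = times, e_eeg = eeg_predictions,
                   e_emg = emg_predictions,
                   bel_right = fused$belief[, "RIGHT"],
                   bel_left = fused$belief[, "LEFT"],
                   bel_stance = fused$belief[, "STANCE"],
                   decision = fused$decision)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
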