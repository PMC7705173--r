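#' Sliding-window specification
#'
#' Rectangular analysis windows with fractional overlap. The defaults —
#' 50 ms windows with 80% overlap — give a decision every
#' `window_length * (1 - overlap)` = 10 ms, i.e. a 100 Hz decision stream.
#' Each window is summarized over its trailing non-overlapping portion
#' (`block_fraction`, default the last 20%), so consecutive decisions
#' summarize disjoint stretches of signal.
#'
#' @param window_length Window length in seconds (default 0.050).
#' @param overlap Fractional overlap between consecutive windows in
#'   `[0, 1)` (default 0.8).
#' @param block_fraction Trailing fraction of each window used for the
#'   block average and the window label, in `(0, 1]` (default 0.2).
#' @return A `window_spec` object.
#' @export
window_spec <- function(window_length = 0.050, overlap = 0.8,
                        block_fraction = 0.2) {
  stopifnot(window_length > 0, overlap >= 0, overlap < 1,
            block_fraction > 0, block_fraction <= 1)
  structure(list(window_length = window_length, overlap = overlap,
                 block_fraction = block_fraction),
            class = "window_spec")
}

#' Window geometry at a given sampling rate
#'
#' Resolves a [window_spec()] into integer sample counts: window length
#' `w = round(window_length * fs)`, step `s = round(w * (1 - overlap))`,
#' block length `round(block_fraction * w)` (at least 1), and the implied
#' decision rate `fs / s` in Hz.
#'
#' @param spec A [window_spec()].
#' @param sampling_rate Hz.
#' @return List with `w`, `step`, `block`, `decision_rate`.
#' @export
window_geometry <- function(spec, sampling_rate) {
  w <- round(spec$window_length * sampling_rate)
  step <- round(w * (1 - spec$overlap))
  if (step < 1L) stop("window step is below one sample at this rate")
  block <- max(1L, round(spec$block_fraction * w))
  list(w = as.integer(w), step = as.integer(step), block = as.integer(block),
       decision_rate = sampling_rate / step)
}

#' Window start indices for a signal of n samples
#'
#' Windows are contiguous slices `[start, start + w - 1]` advancing by the
#' step; the number of windows is `floor((n - w) / step) + 1`.
#'
#' @param n Number of samples.
#' @param spec A [window_spec()].
#' @param sampling_rate Hz.
#' @return Integer vector of 1-based window start indices.
#' @export
window_starts <- function(n, spec, sampling_rate) {
  g <- window_geometry(spec, sampling_rate)
  if (n < g$w) stop("signal shorter than one window")
  n_win <- (n - g$w) %/% g$step + 1L
  seq.int(1L, by = g$step, length.out = n_win)
}

#' Block average of a processed window
#'
#' Per-channel arithmetic mean over the trailing `block_fraction` of the
#' window — the non-overlapping portion that is new relative to the
#' previous window.
#'
#' @param window Numeric matrix (samples x channels) or vector.
#' @param block_fraction Trailing fraction in `(0, 1]`.
#' @return Numeric vector, one value per channel.
#' @export
block_average <- function(window, block_fraction = 0.2) {
  if (is.vector(window)) window <- matrix(window, ncol = 1L)
  stopifnot(block_fraction > 0, block_fraction <= 1)
  w <- nrow(window)
  b <- max(1L, round(block_fraction * w))
  colMeans(window[(w - b + 1L):w, , drop = FALSE])
}

#' Per-window gait labels
#'
#' Assigns each analysis window the majority label over its trailing block
#' — the same samples the block average summarizes, so feature and label
#' describe the same span of signal. Ties go to `STANCE` (ambiguity never
#' commands a step). For the EEG class set, `RIGHT` and `LEFT` collapse
#' to `SWING` before voting.
#'
#' @param labels A [gait_labels()] series aligned with the windowed signal.
#' @param spec A [window_spec()].
#' @param class_set `"gait"` for `{RIGHT, LEFT, STANCE}` or `"eeg"` for
#'   `{SWING, STANCE}`.
#' @return Character vector of per-window labels.
#' @export
window_labels <- function(labels, spec, class_set = c("gait", "eeg")) {
  class_set <- match.arg(class_set)
  stopifnot(inherits(labels, "gait_labels"))
  lab <- labels$labels
  if (class_set == "eeg") lab <- to_eeg_classes(lab)
  classes <- if (class_set == "eeg") EEG_CLASSES else GAIT_CLASSES
  g <- window_geometry(spec, labels$sampling_rate)
  starts <- window_starts(length(lab), spec, labels$sampling_rate)
  ends <- starts + g$w - 1L
  code <- match(lab, classes)
  vapply(seq_along(starts), function(i) {
    blk <- code[(ends[i] - g$block + 1L):ends[i]]
    counts <- tabulate(blk, nbins = length(classes))
    top <- which(counts == max(counts))
    if (length(top) > 1L && match("STANCE", classes) %in% top) {
      classes[match("STANCE", classes)]
    } else {
      classes[top[1L]]
    }
  }, character(1L))
}

#' Window end times in seconds
#'
#' Decision timestamps derive from sample indices: the time of a window is
#' the time of its last sample.
#'
#' @param n Number of samples in the windowed signal.
#' @param spec A [window_spec()].
#' @param sampling_rate Hz.
#' @return Numeric vector of window end times (seconds).
#' @export
window_end_times <- function(n, spec, sampling_rate) {
  g <- window_geometry(spec, sampling_rate)
  starts <- window_starts(n, spec, sampling_rate)
  (starts + g$w - 1L) / sampling_rate
}
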