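#' Multichannel sampled signal
#'
#' Container for a synchronized multichannel time series: a numeric matrix
#' (rows = samples, columns = channels), a sampling rate in Hz, unique
#' channel labels, and a unit string. All gait signals handled by the
#' package (EEG, EMG, foot-switch contacts) are stored in this form.
#'
#' @param samples Numeric matrix, time x channels. A vector is treated as a
#'   single channel.
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param channel_labels Character vector of unique labels, one per column.
#' @param units Unit string, typically `"uV"` for biosignals or `"binary"`
#'   for contact traces.
#' @return An object of class `mcsignal`.
#' @export
multichannel_signal <- function(samples, sampling_rate, channel_labels = NULL,
                                units = "uV") {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  stopifnot(is.matrix(samples), is.numeric(samples))
  if (!all(is.finite(samples))) stop("signal contains non-finite values")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("sampling_rate must be a single positive number")
  }
  if (is.null(channel_labels)) {
    channel_labels <- if (!is.null(colnames(samples))) colnames(samples)
                      else sprintf("ch%02d", seq_len(ncol(samples)))
  }
  if (length(channel_labels) != ncol(samples)) {
    stop("channel_labels length must match number of channels")
  }
  if (anyDuplicated(channel_labels)) stop("channel_labels must be unique")
  colnames(samples) <- channel_labels
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         channel_labels = as.character(channel_labels), units = units),
    class = "mcsignal"
  )
}

#' @export
print.mcsignal <- function(x, ...) {
  cat(sprintf("<mcsignal> %d samples x %d channels @ %g Hz (%.2f s), units: %s\n",
              nrow(x$samples), ncol(x$samples), x$sampling_rate,
              nrow(x$samples) / x$sampling_rate, x$units))
  cat("channels:", paste(x$channel_labels, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.mcsignal <- function(x) dim(x$samples)

n_samples <- function(x) nrow(x$samples)

#' Extract a contiguous sample range of a signal
#'
#' @param x An `mcsignal`.
#' @param from,to First and last sample index (1-based, inclusive).
#' @return An `mcsignal` over the requested range.
#' @export
signal_slice <- function(x, from, to) {
  stopifnot(inherits(x, "mcsignal"), from >= 1L, to <= nrow(x$samples),
            from <= to)
  multichannel_signal(x$samples[from:to, , drop = FALSE], x$sampling_rate,
                      x$channel_labels, x$units)
}

#' Select channels of a signal by label or index
#'
#' @param x An `mcsignal`.
#' @param channels Character vector of labels or integer indices.
#' @return An `mcsignal` holding only the requested channels.
#' @export
signal_select <- function(x, channels) {
  stopifnot(inherits(x, "mcsignal"))
  if (is.character(channels)) {
    missing <- setdiff(channels, x$channel_labels)
    if (length(missing)) {
      stop("unknown channels: ", paste(missing, collapse = ", "))
    }
    idx <- match(channels, x$channel_labels)
  } else {
    idx <- as.integer(channels)
    stopifnot(all(idx >= 1L), all(idx <= ncol(x$samples)))
  }
  multichannel_signal(x$samples[, idx, drop = FALSE], x$sampling_rate,
                      x$channel_labels[idx], x$units)
}

# Gait phase class sets used throughout: the EMG/fused problem discriminates
# the swinging leg, the EEG problem only swing vs double stance.
GAIT_CLASSES <- c("RIGHT", "LEFT", "STANCE")
EEG_CLASSES  <- c("SWING", "STANCE")

#' Per-sample gait phase label series
#'
#' Labels each sample of a walking recording with the fused class set
#' `RIGHT` (right foot in swing), `LEFT` (left foot in swing) or `STANCE`
#' (double support, both feet in contact). Carries per-leg gait-cycle phase
#' (fraction in `[0, 1)` since the leg's last heel strike), which the
#' synthetic EMG generator uses to lock activation bursts to the cycle.
#'
#' @param labels Character vector over `c("RIGHT", "LEFT", "STANCE")`.
#' @param sampling_rate Hz.
#' @param phase_right,phase_left Optional numeric vectors in `[0, 1)`,
#'   same length as `labels`.
#' @return An object of class `gait_labels`.
#' @export
gait_labels <- function(labels, sampling_rate, phase_right = NULL,
                        phase_left = NULL) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), GAIT_CLASSES)
  if (length(bad)) stop("unknown gait labels: ", paste(bad, collapse = ", "))
  for (ph in list(phase_right, phase_left)) {
    if (!is.null(ph)) stopifnot(length(ph) == length(labels))
  }
  structure(
    list(labels = labels, sampling_rate = as.numeric(sampling_rate),
         phase_right = phase_right, phase_left = phase_left),
    class = "gait_labels"
  )
}

#' @export
print.gait_labels <- function(x, ...) {
  tab <- table(factor(x$labels, levels = GAIT_CLASSES))
  cat(sprintf("<gait_labels> %d samples @ %g Hz\n", length(x$labels),
              x$sampling_rate))
  print(round(100 * tab / length(x$labels), 1))
  invisible(x)
}

#' @export
length.gait_labels <- function(x) length(x$labels)

labels_slice <- function(x, from, to) {
  gait_labels(x$labels[from:to], x$sampling_rate,
              if (!is.null(x$phase_right)) x$phase_right[from:to],
              if (!is.null(x$phase_left)) x$phase_left[from:to])
}

#' Collapse leg-specific swing labels to the EEG class set
#'
#' The EEG decoder only distinguishes swing (of either leg) from double
#' stance, so `RIGHT` and `LEFT` both map to `SWING`.
#'
#' @param labels Character vector over the fused class set.
#' @return Character vector over `c("SWING", "STANCE")`.
#' @export
to_eeg_classes <- function(labels) {
  ifelse(labels == "STANCE", "STANCE", "SWING")
}
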