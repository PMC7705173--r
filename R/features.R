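#' Per-window feature sequence
#'
#' One scalar feature per channel per analysis window, with window end
#' times and per-window gait labels. Produced by [eeg_window_features()]
#' and [emg_window_features()]; EEG and EMG sequences extracted from the
#' same signal span with the same [window_spec()] are index-aligned.
#'
#' @param features Numeric matrix, windows x channels.
#' @param window_end_times Numeric vector of window end times (seconds).
#' @param labels Character vector of per-window labels (or `NULL`).
#' @param source `"EEG"` or `"EMG"`.
#' @param sampling_rate Sampling rate of the underlying signal (Hz).
#' @return A `feature_sequence` object.
#' @export
feature_sequence <- function(features, window_end_times, labels = NULL,
                             source = c("EEG", "EMG"), sampling_rate = NA) {
  source <- match.arg(source)
  stopifnot(is.matrix(features), nrow(features) == length(window_end_times))
  if (!is.null(labels)) stopifnot(length(labels) == nrow(features))
  structure(list(features = features, window_end_times = window_end_times,
                 labels = labels, source = source,
                 sampling_rate = sampling_rate),
            class = "feature_sequence")
}

#' @export
print.feature_sequence <- function(x, ...) {
  cat(sprintf("<feature_sequence> %s: %d windows x %d channels\n",
              x$source, nrow(x$features), ncol(x$features)))
  if (!is.null(x$labels)) print(table(x$labels))
  invisible(x)
}

# Digital Butterworth design in zero-pole-gain form (analog prototype
# poles + bilinear transform, both closed-form), paired into second-order
# sections. The cascade realization is numerically essential here: the
# order-8 band-pass becomes an order-16 polynomial whose single-section
# transfer-function form loses ~10 significant digits on 50-sample
# windows.
design_butter <- function(order, cutoff_hz, sampling_rate, type) {
  nyq <- sampling_rate / 2
  if (any(cutoff_hz <= 0) || any(cutoff_hz >= nyq)) {
    stop("filter cutoff must lie strictly inside (0, Nyquist)")
  }
  if (order %% 2 != 0) stop("even design orders only")
  n <- order
  # analog prototype poles on the unit left half-circle
  p <- exp(1i * pi * (2 * seq_len(n) + n - 1) / (2 * n))
  fs2 <- 2
  warped <- 2 * fs2 * tan(pi * (cutoff_hz / nyq) / fs2)
  if (type == "low") {
    p <- warped * p
    z <- complex(0)
    k <- Re(warped^n)
  } else if (type == "high") {
    p <- warped / p
    z <- rep(0 + 0i, n)
    k <- 1
  } else {  # band-pass
    bw <- warped[2] - warped[1]
    wo <- sqrt(prod(warped))
    plp <- p * bw / 2
    p <- c(plp + sqrt(plp^2 - wo^2), plp - sqrt(plp^2 - wo^2))
    z <- rep(0 + 0i, n)
    k <- Re(bw^n)
  }
  # bilinear transform; missing zeros land at z = -1
  k <- k * Re(prod(2 * fs2 - z) / prod(2 * fs2 - p))
  z <- (2 * fs2 + z) / (2 * fs2 - z)
  p <- (2 * fs2 + p) / (2 * fs2 - p)
  z <- c(z, rep(-1 + 0i, length(p) - length(z)))
  zpk_to_sos(z, p, k)
}

# Pair conjugate poles and real zeros into biquads. Zeros here are always
# real (+1 / -1 after the bilinear transform); mixed +1/-1 pairs are
# preferred so each section blocks both band edges. Sections are ordered
# with poles closest to the unit circle last; the overall gain rides on
# the first section.
zpk_to_sos <- function(z, p, k) {
  pos <- sort(p[Im(p) > 1e-9])             # one of each conjugate pair
  reals <- Re(p[abs(Im(p)) <= 1e-9])
  pole_pairs <- lapply(pos, function(pp) c(pp, Conj(pp)))
  if (length(reals)) {
    reals <- sort(reals)
    for (i in seq(1, length(reals), by = 2)) {
      pole_pairs[[length(pole_pairs) + 1L]] <- c(reals[i], reals[i + 1])
    }
  }
  zr <- Re(z)
  plus <- zr[zr > 0]
  minus <- zr[zr <= 0]
  zero_pairs <- list()
  for (s in seq_along(pole_pairs)) {
    if (length(plus) && length(minus)) {
      zero_pairs[[s]] <- c(plus[1], minus[1])
      plus <- plus[-1]; minus <- minus[-1]
    } else if (length(plus) >= 2) {
      zero_pairs[[s]] <- plus[1:2]; plus <- plus[-(1:2)]
    } else if (length(minus) >= 2) {
      zero_pairs[[s]] <- minus[1:2]; minus <- minus[-(1:2)]
    } else stop("zero/pole pairing failed")
  }
  ord <- order(vapply(pole_pairs, function(pp) max(Mod(pp)), numeric(1)))
  sos <- matrix(0, length(pole_pairs), 6)
  for (s in seq_along(ord)) {
    pp <- pole_pairs[[ord[s]]]
    zz <- zero_pairs[[ord[s]]]
    g <- if (s == 1) k else 1
    sos[s, ] <- c(g * c(1, -(zz[1] + zz[2]), zz[1] * zz[2]),
                  1, -Re(pp[1] + pp[2]), Re(pp[1] * pp[2]))
  }
  sos
}

# Reflection-padding length for zero-phase filtering on short windows:
# min(3 * (realized order + 1), n - 1), the realized order being twice
# the number of second-order sections.
default_padlen <- function(sos, n) {
  ord <- 2L * nrow(sos)
  min(3L * (ord + 1L), n - 1L)
}

#' Zero-phase Butterworth filtering
#'
#' Applies a Butterworth filter forward and backward (zero net phase) to
#' each channel, with odd-symmetric reflection padding at both ends so
#' that short segments are handled without large edge transients.
#'
#' @param x Numeric matrix (samples x channels) or vector.
#' @param order Butterworth design order.
#' @param cutoff_hz Cutoff (scalar for low/high-pass, length-2 for
#'   band-pass), in Hz.
#' @param sampling_rate Hz.
#' @param type `"pass"`, `"low"` or `"high"`.
#' @param padlen Reflection padding length; default
#'   `min(3 * (realized order + 1), n - 1)`.
#' @param padtype End-condition padding: `"odd"` (odd-symmetric
#'   reflection, the standard choice for zero-mean signals), `"even"`,
#'   or `"constant"` (for nonnegative envelopes).
#' @return Filtered matrix of the same shape as `x`.
#' @export
zerophase_filter <- function(x, order, cutoff_hz, sampling_rate,
                             type = c("pass", "low", "high"), padlen = NULL,
                             padtype = c("odd", "even", "constant")) {
  type <- match.arg(type)
  padtype <- match.arg(padtype)
  vec <- is.vector(x)
  if (vec) x <- matrix(x, ncol = 1L)
  sos <- design_butter(order, cutoff_hz, sampling_rate, type)
  if (is.null(padlen)) padlen <- default_padlen(sos, nrow(x))
  out <- cpp_sos_filtfilt(x, sos, as.integer(padlen),
                          match(padtype, c("odd", "even", "constant")) - 1L)
  if (vec) drop(out) else out
}

#' Common average reference
#'
#' Subtracts the instantaneous mean across channels from every channel.
#' Idempotent: applying it twice equals applying it once.
#'
#' @param x Numeric matrix, samples x channels (>= 2 channels).
#' @return Re-referenced matrix.
#' @export
car_reference <- function(x) {
  stopifnot(is.matrix(x), ncol(x) >= 2L)
  x - rowMeans(x)
}

#' EEG sliding-window features
#'
#' Online EEG feature path: the signal is segmented into rectangular
#' windows (default 50 ms, 80% overlap); inside each window the channels
#' are re-referenced to the common average, band-passed to the low delta-
#' theta range (default 1-8 Hz) with a zero-phase Butterworth filter
#' (design order 4), z-scored per channel within the window, and block
#' averaged over the trailing non-overlapping portion — one scalar per
#' channel per window, at the 100 Hz decision rate.
#'
#' A channel whose within-window standard deviation is zero yields a zero
#' feature (not `NaN`) for that window.
#'
#' @param eeg An EEG [multichannel_signal()] (>= 2 channels).
#' @param spec A [window_spec()].
#' @param band Pass band in Hz, default `c(1, 8)`.
#' @param filter_order Butterworth design order, default 4.
#' @param labels Optional [gait_labels()] aligned with `eeg`; windows are
#'   then labelled over `{SWING, STANCE}` via [window_labels()].
#' @return A [feature_sequence()] with `source = "EEG"`.
#' @export
eeg_window_features <- function(eeg, spec = window_spec(), band = c(1, 8),
                                filter_order = 4, labels = NULL) {
  stopifnot(inherits(eeg, "mcsignal"))
  if (ncol(eeg$samples) < 2L) {
    stop("common average reference requires at least 2 EEG channels")
  }
  fs <- eeg$sampling_rate
  g <- window_geometry(spec, fs)
  starts <- window_starts(nrow(eeg$samples), spec, fs)
  sos <- design_butter(filter_order, band, fs, "pass")
  padlen <- default_padlen(sos, g$w)
  feats <- cpp_eeg_features(eeg$samples, starts, g$w, g$block, sos, padlen)
  colnames(feats) <- eeg$channel_labels
  wl <- if (!is.null(labels)) window_labels(labels, spec, "eeg")
  feature_sequence(feats, window_end_times(nrow(eeg$samples), spec, fs),
                   wl, "EEG", fs)
}

#' EMG sliding-window features
#'
#' EMG feature path: per window, zero-phase Butterworth band-pass (default
#' 10-250 Hz, design order 8) to strip motion artifacts and high-frequency
#' noise, full-wave rectification, zero-phase low-pass envelope smoothing
#' (default 6 Hz, design order 4), then the block average of the trailing
#' non-overlapping portion. The pipeline is positively homogeneous:
#' scaling the input by `a > 0` scales every feature by exactly `a`, which
#' is how amplitude attenuation propagates to the decoder.
#'
#' @param emg An EMG [multichannel_signal()].
#' @param spec A [window_spec()].
#' @param band Pass band in Hz, default `c(10, 250)`; the upper edge must
#'   lie below Nyquist.
#' @param bp_order Band-pass design order, default 8.
#' @param lp_cut Envelope low-pass cutoff in Hz, default 6.
#' @param lp_order Envelope design order, default 4.
#' @param labels Optional [gait_labels()]; windows are then labelled over
#'   `{RIGHT, LEFT, STANCE}`.
#' @return A [feature_sequence()] with `source = "EMG"`.
#' @export
emg_window_features <- function(emg, spec = window_spec(),
                                band = c(10, 250), bp_order = 8,
                                lp_cut = 6, lp_order = 4, labels = NULL) {
  stopifnot(inherits(emg, "mcsignal"))
  fs <- emg$sampling_rate
  if (band[2] >= fs / 2) stop("EMG band upper edge must be below Nyquist")
  g <- window_geometry(spec, fs)
  starts <- window_starts(nrow(emg$samples), spec, fs)
  bp <- design_butter(bp_order, band, fs, "pass")
  lp <- design_butter(lp_order, lp_cut, fs, "low")
  pad_bp <- default_padlen(bp, g$w)
  pad_lp <- default_padlen(lp, g$w)
  feats <- cpp_emg_features(emg$samples, starts, g$w, g$block,
                            bp, lp, pad_bp, pad_lp)
  colnames(feats) <- emg$channel_labels
  wl <- if (!is.null(labels)) window_labels(labels, spec, "gait")
  feature_sequence(feats, window_end_times(nrow(emg$samples), spec, fs),
                   wl, "EMG", fs)
}
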