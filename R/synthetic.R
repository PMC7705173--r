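#' Gait cycle parameters for the synthetic walking generator
#'
#' Describes an alternating-leg walking pattern: mean gait-cycle duration
#' with optional cycle-to-cycle jitter, per-leg stance fraction, and the
#' phase offset between legs. A stance fraction above 0.5 guarantees two
#' double-support intervals per cycle (walking, not running); the
#' constructor rejects parameter sets whose nominal swing intervals of the
#' two legs would overlap (simultaneous flight).
#'
#' @param cycle_duration Mean gait cycle duration in seconds (default 1.1,
#'   a typical treadmill cadence at moderate speed).
#' @param jitter_sd Standard deviation of per-cycle duration jitter in
#'   seconds; must be below 20% of `cycle_duration` (default 0.02).
#' @param stance_fraction Fraction of the cycle each foot is on the
#'   ground, in (0.5, 0.8) (default 0.6).
#' @param leg_phase_offset Phase lag of the left leg relative to the
#'   right, as a fraction of the cycle (default 0.5, symmetric gait).
#' @param duration Session length in seconds (default 600, i.e. 10 min).
#' @param sampling_rate Hz (default 1000, so 50 ms windows are exactly 50
#'   samples and 10 ms steps exactly 10 samples).
#' @return A `gait_cycle_params` object.
#' @export
gait_cycle_params <- function(cycle_duration = 1.1, jitter_sd = 0.02,
                              stance_fraction = 0.6, leg_phase_offset = 0.5,
                              duration = 600, sampling_rate = 1000) {
  stopifnot(cycle_duration > 0, jitter_sd >= 0,
            stance_fraction > 0.5, stance_fraction < 0.8,
            leg_phase_offset > 0, leg_phase_offset < 1,
            duration > 0, sampling_rate > 0)
  if (jitter_sd >= 0.2 * cycle_duration) {
    stop("jitter_sd must be below 20% of the mean cycle duration")
  }
  p <- structure(list(cycle_duration = cycle_duration, jitter_sd = jitter_sd,
                      stance_fraction = stance_fraction,
                      leg_phase_offset = leg_phase_offset,
                      duration = duration, sampling_rate = sampling_rate),
                 class = "gait_cycle_params")
  # nominal (jitter-free) swing intervals on the unit cycle must not overlap
  grid <- seq(0, 1, length.out = 2000L)
  right_swing <- grid >= stance_fraction
  left_phase <- (grid - leg_phase_offset) %% 1
  left_swing <- left_phase >= stance_fraction
  if (any(right_swing & left_swing)) {
    stop("swing intervals of the two legs overlap (simultaneous flight); ",
         "not a valid walking model")
  }
  p
}

# Draw jittered cycle durations covering `duration` seconds (plus margin).
draw_cycle_durations <- function(params) {
  mu <- params$cycle_duration
  sd <- params$jitter_sd
  n_guess <- ceiling(params$duration / mu) + 10L
  repeat {
    d <- stats::rnorm(n_guess, mu, sd)
    d <- pmin(pmax(d, 0.5 * mu), 1.5 * mu)
    if (sum(d) >= params$duration + 2 * mu) return(d)
    n_guess <- n_guess + 10L
  }
}

# Samples (1-based) whose time (i-1)/fs falls in [from, to).
interval_samples <- function(from, to, fs, n) {
  i0 <- max(1L, as.integer(ceiling(from * fs + 1 - 1e-9)))
  i1 <- min(n, as.integer(ceiling(to * fs + 1 - 1e-9)) - 1L)
  if (i0 > i1) integer(0) else i0:i1
}

#' Simulate foot-switch contact traces and gait-phase labels
#'
#' Generates a square-wave alternating-gait model: the right leg's heel
#' strikes define cycle onsets (the first at time 0); each foot is in
#' contact for `stance_fraction` of its cycle, the left leg lagging by
#' `leg_phase_offset`. Per foot, a heel trace covers the leading 70% of
#' stance and a toe trace the trailing 70% (their union is the full stance,
#' as with physical switches under heel and toes); contact = heel OR toe.
#' Per-sample labels follow the foot-switches: `STANCE` where both feet
#' are down, `RIGHT`/`LEFT` where that foot is off the ground. Samples
#' where jitter leaves both feet off inherit the previous valid label.
#'
#' @param params A [gait_cycle_params()].
#' @param seed Integer seed; identical params + seed give bit-identical
#'   output.
#' @return List with `footswitch` (binary [multichannel_signal()], traces
#'   `heel_R`, `toe_R`, `heel_L`, `toe_L`) and `labels` (a
#'   [gait_labels()] carrying per-leg cycle phase).
#' @export
simulate_footswitch <- function(params, seed) {
  stopifnot(inherits(params, "gait_cycle_params"))
  set.seed(as.integer(seed))
  fs <- params$sampling_rate
  n <- round(params$duration * fs)
  d <- draw_cycle_durations(params)
  starts <- cumsum(c(0, d))[seq_along(d)]   # right heel-strike times
  sf <- params$stance_fraction
  off <- params$leg_phase_offset

  heel <- list(R = logical(n), L = logical(n))
  toe  <- list(R = logical(n), L = logical(n))
  phase <- list(R = rep(NA_real_, n), L = rep(NA_real_, n))

  mark_leg <- function(leg, cyc_starts, cyc_durs) {
    for (k in seq_along(cyc_starts)) {
      t0 <- cyc_starts[k]; dk <- cyc_durs[k]
      if (t0 >= params$duration) break
      st_end <- t0 + sf * dk
      heel[[leg]][interval_samples(t0, t0 + 0.7 * sf * dk, fs, n)] <<- TRUE
      toe[[leg]][interval_samples(t0 + 0.3 * sf * dk, st_end, fs, n)] <<- TRUE
      idx <- interval_samples(t0, t0 + dk, fs, n)
      if (length(idx)) {
        phase[[leg]][idx] <<- ((idx - 1) / fs - t0) / dk
      }
    }
  }
  mark_leg("R", starts, d)
  # the left leg lags by `off` cycles; prepend one virtual cycle so the
  # session opening is covered
  left_starts <- c(starts[1] - d[1] + off * d[1], starts + off * d)
  left_durs <- c(d[1], d)
  mark_leg("L", left_starts, left_durs)

  contact_R <- heel$R | toe$R
  contact_L <- heel$L | toe$L
  lab <- rep(NA_character_, n)
  lab[contact_R & contact_L] <- "STANCE"
  lab[!contact_R & contact_L] <- "RIGHT"
  lab[contact_R & !contact_L] <- "LEFT"
  # both feet off (possible under jitter): carry the previous valid label
  if (anyNA(lab)) {
    if (is.na(lab[1])) lab[1] <- "STANCE"
    for (i in which(is.na(lab))) if (i > 1L) lab[i] <- lab[i - 1L]
  }
  phase$R[is.na(phase$R)] <- 0
  phase$L[is.na(phase$L)] <- 0

  fsw <- multichannel_signal(
    cbind(heel_R = as.numeric(heel$R), toe_R = as.numeric(toe$R),
          heel_L = as.numeric(heel$L), toe_L = as.numeric(toe$L)),
    fs, units = "binary")
  list(footswitch = fsw,
       labels = gait_labels(lab, fs, phase_right = phase$R,
                            phase_left = phase$L))
}

#' Muscle activation model for synthetic EMG
#'
#' One surface-EMG channel is modelled as a sum of gait-phase-locked
#' activation bursts (Gaussian envelopes on the unit cycle, wrapping at 1)
#' multiplying a band-limited carrier, plus white baseline noise.
#'
#' @param muscle One of `"TA"`, `"VM"`, `"BF"` (tibialis anterior, vastus
#'   medialis, biceps femoris).
#' @param side `"right"` or `"left"`.
#' @param activation_centers Burst centres as cycle-phase fractions in
#'   `[0, 1)` (phase 0 = that leg's heel strike).
#' @param activation_widths Burst widths (cycle-phase sd), recycled.
#' @param carrier_band Carrier pass band in Hz (default `c(20, 150)`).
#' @param burst_gain Burst amplitude in uV (default 100).
#' @param baseline_noise_sd Baseline noise sd in uV (default 8).
#' @return A `muscle_model` object.
#' @export
muscle_model <- function(muscle = c("TA", "VM", "BF"),
                         side = c("right", "left"),
                         activation_centers, activation_widths,
                         carrier_band = c(20, 150), burst_gain = 100,
                         baseline_noise_sd = 8) {
  muscle <- match.arg(muscle)
  side <- match.arg(side)
  stopifnot(all(activation_centers >= 0), all(activation_centers < 1),
            all(activation_widths > 0), burst_gain >= 0,
            baseline_noise_sd >= 0, length(carrier_band) == 2L,
            carrier_band[1] > 0, carrier_band[2] > carrier_band[1])
  structure(list(muscle = muscle, side = side,
                 activation_centers = activation_centers,
                 activation_widths = rep_len(activation_widths,
                                             length(activation_centers)),
                 carrier_band = carrier_band, burst_gain = burst_gain,
                 baseline_noise_sd = baseline_noise_sd,
                 label = paste0(muscle, "_", toupper(substr(side, 1, 1)))),
            class = "muscle_model")
}

#' Default six-muscle montage
#'
#' TA, VM and BF of each leg with textbook activation timing relative to
#' that leg's cycle (heel strike at phase 0, toe-off near the stance
#' fraction): TA fires through swing and around heel strike, VM in early
#' stance, BF in late swing.
#'
#' @param burst_gain Burst amplitude in uV (default 100).
#' @param baseline_noise_sd Baseline noise sd in uV (default 8).
#' @param stance_fraction Assumed stance fraction used to place swing
#'   bursts (default 0.6).
#' @return List of six [muscle_model()] objects.
#' @export
default_muscle_models <- function(burst_gain = 100, baseline_noise_sd = 8,
                                  stance_fraction = 0.6) {
  mid_swing <- (stance_fraction + 1) / 2
  out <- list()
  for (side in c("right", "left")) {
    out <- c(out, list(
      muscle_model("TA", side,
                   activation_centers = c(mid_swing, 0.02),
                   activation_widths = c(0.10, 0.04),
                   burst_gain = burst_gain,
                   baseline_noise_sd = baseline_noise_sd),
      muscle_model("VM", side,
                   activation_centers = 0.06, activation_widths = 0.06,
                   burst_gain = burst_gain,
                   baseline_noise_sd = baseline_noise_sd),
      muscle_model("BF", side,
                   activation_centers = 1 - 0.07, activation_widths = 0.05,
                   burst_gain = burst_gain,
                   baseline_noise_sd = baseline_noise_sd)))
  }
  out
}

# Gaussian bump envelope on the wrapped unit cycle.
burst_envelope <- function(phase, centers, widths) {
  env <- numeric(length(phase))
  for (j in seq_along(centers)) {
    dist <- abs(phase - centers[j])
    dist <- pmin(dist, 1 - dist)
    env <- env + exp(-0.5 * (dist / widths[j])^2)
  }
  env
}

# Unit-variance band-limited Gaussian carrier.
bandlimited_noise <- function(n, band, fs) {
  x <- zerophase_filter(stats::rnorm(n), 4, band, fs, "pass")
  x / stats::sd(x)
}

#' Simulate gait-locked surface EMG
#'
#' Each channel is `burst_gain * envelope(phase) * carrier + baseline`,
#' where the envelope is locked to that leg's gait-cycle phase (carried by
#' the label series), the carrier is unit-variance band-limited Gaussian
#' noise, and the baseline is white noise. Burst timing is phase-locked so
#' a decoder can separate the swinging leg from double stance.
#'
#' @param labels A [gait_labels()] from [simulate_footswitch()] (must
#'   carry per-leg phase).
#' @param muscles List of [muscle_model()]s (default
#'   [default_muscle_models()]).
#' @param seed Integer seed.
#' @param sampling_rate Hz; defaults to the label series' rate.
#' @return An EMG [multichannel_signal()] (uV).
#' @export
simulate_emg <- function(labels, muscles = default_muscle_models(), seed,
                         sampling_rate = labels$sampling_rate) {
  stopifnot(inherits(labels, "gait_labels"),
            !is.null(labels$phase_right), !is.null(labels$phase_left))
  set.seed(as.integer(seed))
  n <- length(labels$labels)
  fs <- sampling_rate
  out <- matrix(0, n, length(muscles))
  lbl <- character(length(muscles))
  for (m in seq_along(muscles)) {
    mu <- muscles[[m]]
    if (mu$carrier_band[2] >= fs / 2) {
      stop("carrier band of ", mu$label, " reaches Nyquist")
    }
    phase <- if (mu$side == "right") labels$phase_right else labels$phase_left
    env <- burst_envelope(phase, mu$activation_centers, mu$activation_widths)
    carrier <- bandlimited_noise(n, mu$carrier_band, fs)
    out[, m] <- mu$burst_gain * env * carrier +
      stats::rnorm(n, 0, mu$baseline_noise_sd)
    lbl[m] <- mu$label
  }
  multichannel_signal(out, fs, lbl, units = "uV")
}

#' Cortical model for synthetic EEG
#'
#' The scalp signal is modelled as a gait-locked low-frequency component
#' plus 1/f-like background noise. The gait-locked component is shared
#' across channels with a channel-specific gain (largest over central,
#' midline channels) and carries swing-vs-stance information only — it is
#' identical for right-leg and left-leg swing, reflecting that low-
#' frequency cortical gait correlates mark stepping, not its side. It has
#' three parts, all scaled by `modulation_contrast`: a deterministic
#' step-onset-locked waveform (an evoked-potential-like bump at each
#' swing onset), amplitude modulation of the low-frequency carrier (band
#' power higher in swing than in stance), and a spectral shift of the
#' carrier within the gait-locked band (slower delta-range activity in
#' double support, faster theta-range activity in swing).
#' `modulation_contrast = 0` makes the EEG label-independent.
#'
#' @param n_channels Number of channels (default 16).
#' @param gait_locked_band Hz pair inside 1-8 (default `c(1.5, 6)`).
#' @param locking_gain Per-channel gains in uV; default a spatial bump
#'   peaked at the central channel with peak `peak_gain`.
#' @param peak_gain Peak locking gain in uV (default 18; the synthetic
#'   EEG emulates recordings already cleaned of gait artifacts, where
#'   step-locked low-frequency potentials stand well above the residual
#'   background).
#' @param background_sd Background noise sd in uV (default 4).
#' @param background_exponent Spectral exponent of the 1/f^a background
#'   (default 1).
#' @param modulation_contrast Unitless swing-vs-stance contrast
#'   (default 2).
#' @return A `cortical_model` object.
#' @export
cortical_model <- function(n_channels = 16, gait_locked_band = c(1.5, 6),
                           locking_gain = NULL, peak_gain = 18,
                           background_sd = 4, background_exponent = 1,
                           modulation_contrast = 2) {
  stopifnot(n_channels >= 2, length(gait_locked_band) == 2L,
            gait_locked_band[1] >= 1, gait_locked_band[2] <= 8,
            gait_locked_band[1] < gait_locked_band[2],
            background_sd >= 0, modulation_contrast >= 0)
  if (is.null(locking_gain)) {
    centre <- (n_channels + 1) / 2
    locking_gain <- peak_gain *
      exp(-0.5 * ((seq_len(n_channels) - centre) / (n_channels / 5))^2)
  }
  stopifnot(length(locking_gain) == n_channels, all(locking_gain >= 0),
            any(locking_gain > 0))
  structure(list(n_channels = n_channels,
                 gait_locked_band = gait_locked_band,
                 locking_gain = locking_gain,
                 background_sd = background_sd,
                 background_exponent = background_exponent,
                 modulation_contrast = modulation_contrast),
            class = "cortical_model")
}

# 1/f^a-shaped Gaussian noise via spectral shaping, scaled to sd `sd`.
one_over_f_noise <- function(n, fs, sd, exponent) {
  if (sd == 0) return(numeric(n))
  white <- stats::rnorm(n)
  if (exponent == 0) return(sd * white)
  spec <- stats::fft(white)
  freq <- c(0, pmin(seq_len(n - 1), n - seq_len(n - 1))) * fs / n
  shape <- 1 / pmax(freq, 1)^(exponent / 2)  # flatten below 1 Hz
  shape[1] <- 0
  x <- Re(stats::fft(spec * shape, inverse = TRUE)) / n
  sd * x / stats::sd(x)
}

#' Simulate gait-locked EEG
#'
#' @param labels A [gait_labels()] series.
#' @param cortical A [cortical_model()].
#' @param seed Integer seed.
#' @param sampling_rate Hz; defaults to the label series' rate.
#' @return An EEG [multichannel_signal()] (uV) with channels
#'   `eeg01 ... eegNN`.
#' @export
simulate_eeg <- function(labels, cortical = cortical_model(), seed,
                         sampling_rate = labels$sampling_rate) {
  stopifnot(inherits(labels, "gait_labels"),
            inherits(cortical, "cortical_model"))
  set.seed(as.integer(seed))
  n <- length(labels$labels)
  fs <- sampling_rate
  swing <- as.numeric(labels$labels != "STANCE")
  ctr <- cortical$modulation_contrast

  # deterministic evoked-like waveform: a smooth bump shortly after every
  # step onset (transition into swing of either leg), peak-normalized —
  # power locked inside swing periods, identical for right and left
  # steps; the 80 ms delay keeps the zero-phase bump tails from leaking
  # into the preceding double support
  onsets <- which(diff(swing) > 0) + 1L + round(0.08 * fs)
  onsets <- onsets[onsets <= n]
  ev <- numeric(n)
  ev[onsets] <- 1
  d <- zerophase_filter(ev, 4, cortical$gait_locked_band[2], fs, "low")
  if (max(abs(d)) > 0) d <- d / max(abs(d))

  # gait-locked carrier: the contrast shifts both the amplitude (larger
  # in swing) and the dominant frequency of the locked component — slow
  # delta-range activity during double support, faster theta-range
  # activity during swing. The spectral shift is what remains visible
  # after the per-window z-scoring of the decoding pipeline, which is
  # amplitude-blind by construction.
  band <- cortical$gait_locked_band
  split_hz <- mean(band)
  c_lo <- bandlimited_noise(n, c(band[1], split_hz), fs)
  c_hi <- bandlimited_noise(n, c(split_hz, band[2]), fs)
  w_sm <- zerophase_filter(swing, 4, 2, fs, "low")
  w_sm <- pmin(pmax(w_sm, 0), 1)
  lambda <- 0.5 + min(ctr, 1) * (w_sm - 0.5)   # 0.5 everywhere at ctr = 0
  carrier <- (1 - lambda) * c_lo + lambda * c_hi
  locked <- ctr * d + (1 + ctr * swing) * carrier

  out <- matrix(0, n, cortical$n_channels)
  for (ch in seq_len(cortical$n_channels)) {
    out[, ch] <- cortical$locking_gain[ch] * locked +
      one_over_f_noise(n, fs, cortical$background_sd,
                       cortical$background_exponent)
  }
  multichannel_signal(out, fs,
                      sprintf("eeg%02d", seq_len(cortical$n_channels)),
                      units = "uV")
}

#' Simulate a complete synthetic walking session
#'
#' Foot-switch contacts and labels, gait-locked EMG, and gait-locked EEG,
#' all synchronized at the same sampling rate. Sub-seeds for the three
#' generators are derived from `seed` so the whole session is reproducible
#' bit-for-bit.
#'
#' @param params A [gait_cycle_params()].
#' @param muscles List of [muscle_model()]s.
#' @param cortical A [cortical_model()].
#' @param seed Integer seed (one seed = one synthetic "subject").
#' @return A `gait_session` object with elements `eeg`, `emg`,
#'   `footswitch`, `labels`, `seed`, `params`.
#' @export
simulate_session <- function(params = gait_cycle_params(),
                             muscles = default_muscle_models(
                               stance_fraction = params$stance_fraction),
                             cortical = cortical_model(), seed = 1L) {
  seed <- as.integer(seed)
  fw <- simulate_footswitch(params, seed)
  emg <- simulate_emg(fw$labels, muscles, seed = (seed + 1L) %% .Machine$integer.max)
  eeg <- simulate_eeg(fw$labels, cortical, seed = (seed + 2L) %% .Machine$integer.max)
  structure(list(eeg = eeg, emg = emg, footswitch = fw$footswitch,
                 labels = fw$labels, seed = seed,
                 params = list(gait = params, muscles = muscles,
                               cortical = cortical)),
            class = "gait_session")
}

#' @export
print.gait_session <- function(x, ...) {
  cat(sprintf("<gait_session> seed %d, %.1f s @ %g Hz\n", x$seed,
              length(x$labels) / x$labels$sampling_rate,
              x$labels$sampling_rate))
  cat(sprintf("  eeg: %d ch | emg: %d ch | footswitch: %d traces\n",
              ncol(x$eeg$samples), ncol(x$emg$samples),
              ncol(x$footswitch$samples)))
  print(x$labels)
  invisible(x)
}
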