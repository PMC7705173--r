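#' Linear amplitude attenuation
#'
#' Multiplies every EMG sample by a retained-amplitude fraction. An
#' attenuation "of X%" corresponds to `fraction = 1 - X/100` (e.g. an
#' attenuation of 70% retains 30% of the amplitude). Because the EMG
#' feature pipeline is positively homogeneous, downstream features scale
#' by exactly the same fraction.
#'
#' @param emg An EMG [multichannel_signal()].
#' @param fraction Retained amplitude fraction in `(0, 1]`.
#' @return The attenuated signal; the applied fraction is recorded in
#'   attribute `"attenuation"` (multiplicative across applications).
#' @export
attenuate <- function(emg, fraction) {
  stopifnot(inherits(emg, "mcsignal"))
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction <= 0 || fraction > 1) {
    stop("fraction must lie in (0, 1]")
  }
  out <- multichannel_signal(emg$samples * fraction, emg$sampling_rate,
                             emg$channel_labels, emg$units)
  prev <- attr(emg, "attenuation")
  attr(out, "attenuation") <- if (is.null(prev)) fraction else prev * fraction
  out
}

#' Additive Gaussian noise at a target signal-to-noise ratio
#'
#' Adds i.i.d. zero-mean Gaussian noise per channel with standard
#' deviation `sigma = sqrt(P_signal / 10^(SNR_dB / 10))`, where
#' `P_signal` is that channel's mean squared amplitude over the whole
#' recording (computed after any attenuation). The empirical SNR of the
#' output converges to the target as the sample count grows.
#'
#' @param emg An EMG [multichannel_signal()] with nonzero power on every
#'   channel.
#' @param target_snr_db Target SNR in dB.
#' @param seed Integer seed for the noise draw.
#' @return The noisy signal; target SNR and seed are recorded in
#'   attribute `"noise"`.
#' @export
add_noise_at_snr <- function(emg, target_snr_db, seed) {
  stopifnot(inherits(emg, "mcsignal"))
  set.seed(as.integer(seed))
  x <- emg$samples
  p_signal <- colMeans(x^2)
  if (any(p_signal == 0)) {
    stop("zero-power channel(s): ",
         paste(emg$channel_labels[p_signal == 0], collapse = ", "))
  }
  sigma <- sqrt(p_signal / 10^(target_snr_db / 10))
  noise <- matrix(stats::rnorm(length(x)), nrow(x), ncol(x))
  noise <- sweep(noise, 2, sigma, "*")
  out <- multichannel_signal(x + noise, emg$sampling_rate,
                             emg$channel_labels, emg$units)
  attr(out, "attenuation") <- attr(emg, "attenuation")
  attr(out, "noise") <- list(target_snr_db = target_snr_db, seed = seed)
  out
}

#' Temporary EMG impairment regime (fatigue-like)
#'
#' Linear amplitude attenuation applied at interface-usage time only: the
#' training split is never altered (the decoder was calibrated on intact
#' muscles), while the validation and test splits are attenuated — by
#' independently configurable fractions, so the robustness protocol where
#' calibration and usage attenuation differ by +-10 percentage points can
#' be expressed.
#'
#' @param retained_fraction Retained amplitude fraction for the test
#'   split, in `(0, 1]` (study conditions: 1.0, 0.9, 0.5, 0.3, 0.1).
#' @param validation_fraction Retained fraction for the validation split;
#'   defaults to `retained_fraction`.
#' @return A `temporary_alteration` object.
#' @export
temporary_alteration <- function(retained_fraction,
                                 validation_fraction = retained_fraction) {
  stopifnot(retained_fraction > 0, retained_fraction <= 1,
            validation_fraction > 0, validation_fraction <= 1)
  structure(list(retained_fraction = retained_fraction,
                 validation_fraction = validation_fraction),
            class = c("temporary_alteration", "alteration"))
}

#' Permanent EMG impairment regime (paresis-like)
#'
#' Simulates a lasting muscular impairment: only a subset of muscles
#' remains usable (by default the vastus medialis of each leg), the
#' retained channels are attenuated (default to 30% of their amplitude,
#' i.e. a 70% attenuation), and Gaussian noise is added at a target SNR.
#' The regime applies to training, validation and test splits alike — the
#' impairment does not change between calibration and usage.
#'
#' @param retained_channels Channel labels kept (default
#'   `c("VM_R", "VM_L")`).
#' @param retained_fraction Retained amplitude fraction (default 0.3).
#' @param target_snr_db Target SNR in dB (study conditions: 10, 3, 1.5,
#'   1, 0.5, 0.1), or `NA` for no added noise.
#' @param noise_seed Seed for the noise draw (default 1).
#' @return A `permanent_alteration` object.
#' @export
permanent_alteration <- function(retained_channels = c("VM_R", "VM_L"),
                                 retained_fraction = 0.3,
                                 target_snr_db = NA, noise_seed = 1L) {
  stopifnot(length(retained_channels) >= 1,
            retained_fraction > 0, retained_fraction <= 1)
  structure(list(retained_channels = retained_channels,
                 retained_fraction = retained_fraction,
                 target_snr_db = target_snr_db,
                 noise_seed = as.integer(noise_seed)),
            class = c("permanent_alteration", "alteration"))
}

#' Apply an impairment regime to EMG session splits
#'
#' Takes the three time-ordered EMG splits and returns them altered
#' according to the regime. Temporary regime: training untouched,
#' validation and test attenuated. Permanent regime: channel subsetting,
#' then attenuation, then noise at the target SNR (noise sd computed per
#' split from the attenuated split), on all three splits; split-specific
#' sub-seeds keep the draws independent.
#'
#' @param splits List with EMG [multichannel_signal()]s named `train`,
#'   `validation`, `test`.
#' @param regime A [temporary_alteration()] or [permanent_alteration()].
#' @return List of altered splits with the same names.
#' @export
apply_experiment <- function(splits, regime) {
  stopifnot(is.list(splits),
            all(c("train", "validation", "test") %in% names(splits)))
  if (!inherits(regime, "alteration")) {
    stop("regime must be a temporary_alteration or permanent_alteration")
  }
  if (inherits(regime, "temporary_alteration")) {
    list(train = splits$train,
         validation = if (regime$validation_fraction < 1) {
           attenuate(splits$validation, regime$validation_fraction)
         } else splits$validation,
         test = if (regime$retained_fraction < 1) {
           attenuate(splits$test, regime$retained_fraction)
         } else splits$test)
  } else {
    one <- function(x, sub) {
      x <- signal_select(x, regime$retained_channels)
      x <- attenuate(x, regime$retained_fraction)
      if (!is.na(regime$target_snr_db)) {
        x <- add_noise_at_snr(x, regime$target_snr_db,
                              seed = regime$noise_seed + sub)
      }
      x
    }
    list(train = one(splits$train, 0L),
         validation = one(splits$validation, 1L),
         test = one(splits$test, 2L))
  }
}
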