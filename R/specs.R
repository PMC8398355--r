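#' Acquisition specification for multichannel sEMG trials
#'
#' Describes the recording protocol emulated by the synthetic generator:
#' sampling rate, trial duration, channel count (one per muscle), number of
#' movement classes and number of subjects. Defaults mirror a typical
#' upper-limb rehabilitation protocol: 4 muscles sampled at 2048 Hz for 5 s,
#' 12 movement classes, 14 subjects.
#'
#' @param sampling_rate Sampling rate in Hz.
#' @param duration Trial duration in seconds.
#' @param n_channels Number of recording channels (muscles).
#' @param n_classes Number of movement classes.
#' @param trials_per_class_per_subject Repetitions of each movement per subject.
#' @param n_subjects Number of subjects.
#'
#' @return An object of class `acquisition_spec`.
#' @examples
#' acq <- acquisition_spec()
#' samples_per_trial(acq) # 10240
#' @export
acquisition_spec <- function(sampling_rate = 2048, duration = 5,
                             n_channels = 4, n_classes = 12,
                             trials_per_class_per_subject = 5,
                             n_subjects = 14) {
  stopifnot(sampling_rate > 0, duration > 0)
  counts <- c(n_channels, n_classes, trials_per_class_per_subject, n_subjects)
  if (any(counts < 1) || any(counts != round(counts))) {
    stop("channel/class/trial/subject counts must be integers >= 1", call. = FALSE)
  }
  structure(
    list(
      sampling_rate = sampling_rate,
      duration = duration,
      n_channels = as.integer(n_channels),
      n_classes = as.integer(n_classes),
      trials_per_class_per_subject = as.integer(trials_per_class_per_subject),
      n_subjects = as.integer(n_subjects)
    ),
    class = "acquisition_spec"
  )
}

#' Samples per trial implied by an acquisition spec
#'
#' @param acq An [acquisition_spec()].
#' @return Integer sample count, `round(sampling_rate * duration)`.
#' @export
samples_per_trial <- function(acq) {
  stopifnot(inherits(acq, "acquisition_spec"))
  as.integer(round(acq$sampling_rate * acq$duration))
}

#' Noise specification for synthetic sEMG
#'
#' Amplitudes of the three noise components added to every synthetic channel:
#' a broadband baseline floor, 50 Hz powerline interference, and slow
#' (sub-6 Hz) motion-artifact drift. All amplitudes are in the same arbitrary
#' units as the signal; set any of them to 0 to disable that component.
#'
#' @param baseline_rms RMS of the white baseline noise floor.
#' @param powerline_amplitude Amplitude of the 50 Hz sinusoidal interference.
#' @param drift_amplitude Amplitude of the sub-6 Hz random drift.
#' @param powerline_freq Interference frequency in Hz (50 in most grids).
#'
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(baseline_rms = 0.05, powerline_amplitude = 0.5,
                       drift_amplitude = 0.5, powerline_freq = 50) {
  amps <- c(baseline_rms, powerline_amplitude, drift_amplitude)
  if (any(!is.finite(amps)) || any(amps < 0)) {
    stop("noise amplitudes must be finite and >= 0", call. = FALSE)
  }
  stopifnot(powerline_freq > 0)
  structure(
    list(
      baseline_rms = baseline_rms,
      powerline_amplitude = powerline_amplitude,
      drift_amplitude = drift_amplitude,
      powerline_freq = powerline_freq
    ),
    class = "noise_spec"
  )
}

#' Per-class activation profile
#'
#' Encodes how one movement class drives the recorded muscles: a per-channel
#' envelope gain, a per-channel carrier band (the frequency band the channel's
#' band-limited activity occupies, inside the 6--500 Hz sEMG band), and the
#' onset/offset of the contraction envelope as fractions of the trial.
#'
#' @param gains Numeric vector of per-channel envelope gains (>= 0).
#' @param bands Matrix `[n_channels x 2]` of (low, high) carrier-band edges in
#'   Hz, each row within \[6, 500\].
#' @param onset,offset Envelope onset/offset as fractions of trial duration.
#'
#' @return An object of class `activation_profile`.
#' @export
activation_profile <- function(gains, bands, onset = 0.1, offset = 0.9) {
  gains <- as.numeric(gains)
  bands <- matrix(as.numeric(bands), ncol = 2)
  if (length(gains) < 1) stop("need at least one channel", call. = FALSE)
  if (nrow(bands) != length(gains)) {
    stop("one band per channel required", call. = FALSE)
  }
  if (any(!is.finite(gains)) || any(gains < 0)) {
    stop("gains must be finite and >= 0", call. = FALSE)
  }
  if (any(bands[, 1] >= bands[, 2])) stop("band low must be < band high", call. = FALSE)
  if (any(bands < 6) || any(bands > 500)) {
    stop("carrier bands must lie within [6, 500] Hz", call. = FALSE)
  }
  stopifnot(onset >= 0, offset <= 1, onset < offset)
  structure(
    list(gains = gains, bands = bands, onset = onset, offset = offset),
    class = "activation_profile"
  )
}

#' @export
print.acquisition_spec <- function(x, ...) {
  cat("<acquisition_spec> ", x$n_channels, " ch @ ", x$sampling_rate, " Hz, ",
      x$duration, " s (", samples_per_trial(x), " samples), ",
      x$n_classes, " classes, ", x$n_subjects, " subjects, ",
      x$trials_per_class_per_subject, " trials/class/subject\n", sep = "")
  invisible(x)
}

#' @export
print.activation_profile <- function(x, ...) {
  cat("<activation_profile> gains:", paste(signif(x$gains, 3), collapse = ", "),
      "\n  bands (Hz):",
      paste(apply(x$bands, 1, function(b) sprintf("[%g, %g]", b[1], b[2])),
            collapse = " "),
      sprintf("\n  envelope: %.0f%%-%.0f%% of trial\n", 100 * x$onset, 100 * x$offset))
  invisible(x)
}
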