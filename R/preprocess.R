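# Denoising: 50 Hz powerline notch + 6 Hz high-pass, zero-phase by default.

#' Filter specification for sEMG denoising
#'
#' A narrow second-order IIR notch at the powerline frequency plus a
#' Butterworth high-pass that removes sub-6 Hz motion artifacts while keeping
#' the 6--500 Hz sEMG band. Zero-phase (forward-backward) application is the
#' default so the time-frequency representation inherits no phase distortion;
#' note that forward-backward filtering squares the magnitude response.
#'
#' @param notch_freq Notch centre frequency in Hz.
#' @param notch_q Notch quality factor (centre / -3 dB bandwidth); Q = 30
#'   keeps the adjacent 45--55 Hz sEMG content.
#' @param highpass_cutoff High-pass cutoff in Hz.
#' @param highpass_order Butterworth order (per pass).
#' @param zero_phase Apply filters forward-backward (no group delay)?
#' @return An object of class `filter_spec`.
#' @export
filter_spec <- function(notch_freq = 50, notch_q = 30,
                        highpass_cutoff = 6, highpass_order = 4,
                        zero_phase = TRUE) {
  stopifnot(notch_q > 0, highpass_order >= 1,
            highpass_cutoff > 0, highpass_cutoff < notch_freq)
  structure(
    list(notch_freq = notch_freq, notch_q = notch_q,
         highpass_cutoff = highpass_cutoff,
         highpass_order = as.integer(highpass_order),
         zero_phase = isTRUE(zero_phase)),
    class = "filter_spec"
  )
}

# Biquad notch coefficients (constrained second-order IIR with zeros on the
# unit circle at +-w0 and poles just inside, bandwidth w0/Q).
notch_coefficients <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1], a = a / a[1])
}

# Forward-backward filtering with odd-reflection padding so startup
# transients settle outside the retained samples (narrow notches ring for
# seconds otherwise).
apply_iir <- function(x, b, a, zero_phase, pad = 0) {
  if (!zero_phase) {
    return(as.numeric(signal::filter(signal::Arma(b = b, a = a), x)))
  }
  n <- length(x)
  pad <- min(pad, n - 1)
  xp <- if (pad > 0) {
    c(2 * x[1] - x[(pad + 1):2], x, 2 * x[n] - x[(n - 1):(n - pad)])
  } else x
  y <- as.numeric(signal::filtfilt(signal::Arma(b = b, a = a), xp))
  if (pad > 0) y[(pad + 1):(pad + n)] else y
}

check_signal <- function(x, fs) {
  if (!is.numeric(x) || length(x) == 0) stop("signal must be non-empty numeric", call. = FALSE)
  if (any(!is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  if (fs <= 100) stop("sampling rate must exceed 100 Hz", call. = FALSE)
  invisible(TRUE)
}

#' Notch out powerline interference
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param spec A [filter_spec()].
#' @return Filtered vector, same length as `x`.
#' @examples
#' fs <- 2048
#' t <- seq(0, 1, by = 1 / fs)
#' y <- notch50(sin(2 * pi * 50 * t), fs)
#' sqrt(mean(y^2)) # ~0
#' @export
notch50 <- function(x, fs, spec = filter_spec()) {
  check_signal(x, fs)
  co <- notch_coefficients(spec$notch_freq, fs, spec$notch_q)
  # ring-down time constant ~ fs * Q / (pi * f0); pad three of them
  pad <- ceiling(3 * fs * spec$notch_q / (pi * spec$notch_freq))
  apply_iir(x, co$b, co$a, spec$zero_phase, pad = pad)
}

#' High-pass filter out motion-artifact drift
#'
#' Butterworth high-pass at `spec$highpass_cutoff` (6 Hz by default),
#' removing DC and slow drift while keeping the sEMG band.
#'
#' @inheritParams notch50
#' @return Filtered vector, same length as `x`.
#' @export
highpass6 <- function(x, fs, spec = filter_spec()) {
  check_signal(x, fs)
  bt <- signal::butter(spec$highpass_order, spec$highpass_cutoff / (fs / 2),
                       type = "high")
  apply_iir(x, bt$b, bt$a, spec$zero_phase,
            pad = ceiling(3 * fs / spec$highpass_cutoff))
}

#' Preprocess a trial (notch, then high-pass, channel-wise)
#'
#' Applies [notch50()] then [highpass6()] to every channel and flags the
#' trial as preprocessed. Re-preprocessing an already-flagged trial warns and
#' returns it unchanged (idempotent by flag).
#'
#' @param trial A `semg_trial`.
#' @param spec A [filter_spec()].
#' @return The filtered `semg_trial`.
#' @export
preprocess_trial <- function(trial, spec = filter_spec()) {
  stopifnot(inherits(trial, "semg_trial"))
  if (isTRUE(trial$preprocessed)) {
    warning("trial already preprocessed; returning unchanged")
    return(trial)
  }
  fs <- trial$acq$sampling_rate
  trial$data <- t(apply(trial$data, 1, function(ch) {
    highpass6(notch50(ch, fs, spec), fs, spec)
  }))
  trial$preprocessed <- TRUE
  trial
}

#' Preprocess every trial of a dataset
#'
#' @param dataset A `semg_dataset`.
#' @param spec A [filter_spec()].
#' @return The dataset with all channels filtered and flagged preprocessed.
#' @export
preprocess_dataset <- function(dataset, spec = filter_spec()) {
  stopifnot(inherits(dataset, "semg_dataset"))
  if (isTRUE(dataset$preprocessed)) {
    warning("dataset already preprocessed; returning unchanged")
    return(dataset)
  }
  fs <- dataset$acq$sampling_rate
  dataset$trials$data <- lapply(dataset$trials$data, function(m) {
    t(apply(m, 1, function(ch) highpass6(notch50(ch, fs, spec), fs, spec)))
  })
  dataset$preprocessed <- TRUE
  dataset
}
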