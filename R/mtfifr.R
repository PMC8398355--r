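# Multiscale time-frequency information fusion representation:
# per-channel analytic-Morlet CWT over 6-500 Hz, vertical concatenation of
# the channel scalograms, rendering to a fixed-size 3-plane image.

#' Analytic Morlet wavelet specification
#'
#' The analytic Morlet wavelet has no negative-frequency content, so its CWT
#' magnitude is a smooth envelope. Its frequency response at scale s peaks at
#' omega0 / s rad/sample; `omega0 = 6` is the common default and gives
#' centre frequency `omega0 / (2 pi)` cycles.
#'
#' @param omega0 Dimensionless centre angular frequency (> 0).
#' @return An object of class `wavelet_spec`.
#' @export
wavelet_spec <- function(omega0 = 6) {
  stopifnot(omega0 > 0)
  structure(list(omega0 = omega0, center_frequency = omega0 / (2 * pi)),
            class = "wavelet_spec")
}

#' Frequency grid for the multiscale decomposition
#'
#' One analysis scale per grid frequency, covering the functional sEMG band
#' (6--500 Hz by default, 1 Hz spacing). Each scale is chosen so that its
#' pseudo-frequency (the peak of the wavelet's frequency response) equals the
#' grid frequency: `s_i = omega0 * fs / (2 pi f_i)`, in samples. Scales are
#' therefore strictly decreasing as frequency increases.
#'
#' @param f_lo,f_hi Band edges in Hz; `6 <= f_lo < f_hi <= fs/2`.
#' @param step Grid spacing in Hz.
#' @param fs Sampling rate in Hz.
#' @param wavelet A [wavelet_spec()].
#' @return An object of class `frequency_grid` with `frequencies` (ascending)
#'   and `scales` (samples, one per frequency).
#' @examples
#' g <- make_grid(6, 500, 1, 2048)
#' length(g$frequencies) # 495
#' @export
make_grid <- function(f_lo = 6, f_hi = 500, step = 1, fs = 2048,
                      wavelet = wavelet_spec()) {
  stopifnot(step > 0, f_lo > 0, f_lo < f_hi)
  if (f_hi > fs / 2) {
    stop("f_hi exceeds the Nyquist frequency fs/2", call. = FALSE)
  }
  freqs <- seq(f_lo, f_hi, by = step)
  scales <- wavelet$omega0 * fs / (2 * pi * freqs)
  structure(
    list(f_lo = f_lo, f_hi = f_hi, step = step, fs = fs,
         frequencies = freqs, scales = scales, wavelet = wavelet),
    class = "frequency_grid"
  )
}

#' Multiscale decomposition of a single channel (CWT scalogram)
#'
#' FFT-based continuous wavelet transform with the analytic Morlet wavelet:
#' for each scale the signal spectrum is multiplied by the (real,
#' non-negative) wavelet response `exp(-(s*omega - omega0)^2 / 2)` restricted
#' to positive frequencies, and inverse-transformed. Scales are
#' L1-normalized, so a unit tone has the same peak magnitude at every scale
#' and its magnitude maximum falls on the scale whose pseudo-frequency
#' matches the tone frequency. The signal is
#' zero-padded past the widest wavelet's support to suppress circular
#' wrap-around; cone-of-influence columns are retained, not masked.
#'
#' @param x Numeric signal vector.
#' @param fs Sampling rate in Hz.
#' @param grid A [frequency_grid()] (its `fs` must match).
#' @param channel_id Optional channel label stored with the result.
#' @return An object of class `scalogram`: list with `magnitude`
#'   (`[n_freqs x n_samples]`, rows ordered as `grid$frequencies`), `grid`,
#'   `channel_id`.
#' @examples
#' g <- make_grid(6, 200, 2, 512)
#' s <- mdtfr(sin(2 * pi * 50 * seq(0, 1, by = 1 / 512)), 512, g)
#' g$frequencies[which.max(rowMeans(s$magnitude))] # ~50
#' @export
mdtfr <- function(x, fs, grid, channel_id = NA_integer_) {
  if (length(x) == 0) stop("empty signal", call. = FALSE)
  if (any(!is.finite(x))) stop("signal contains non-finite values", call. = FALSE)
  stopifnot(inherits(grid, "frequency_grid"))
  if (!isTRUE(all.equal(fs, grid$fs))) {
    stop("sampling rate does not match the frequency grid", call. = FALSE)
  }
  n <- length(x)
  omega0 <- grid$wavelet$omega0
  pad <- ceiling(4 * max(grid$scales))
  npad <- stats::nextn(n + 2 * pad, c(2, 3, 5))
  fx <- stats::fft(c(x, rep(0, npad - n)))
  omega <- 2 * pi * (seq_len(npad) - 1) / npad # rad/sample, 0..2pi
  pos <- omega <= pi # analytic: positive-frequency half only
  # columns: L1-normalized wavelet response at each scale
  psi <- vapply(grid$scales, function(s) {
    w <- numeric(npad)
    w[pos] <- exp(-0.5 * (s * omega[pos] - omega0)^2)
    w
  }, numeric(npad))
  coef <- stats::mvfft(psi * as.vector(fx), inverse = TRUE) / npad
  mag <- t(Mod(coef[seq_len(n), , drop = FALSE]))
  structure(list(magnitude = mag, grid = grid, channel_id = channel_id),
            class = "scalogram")
}

#' Fuse per-channel scalograms by vertical concatenation
#'
#' Stacks the channel scalogram magnitudes top-to-bottom (CH1 block first),
#' giving one `[(n_channels * n_freqs) x n_samples]` time-frequency matrix
#' for the whole trial.
#'
#' @param scalograms List of [mdtfr()] results sharing grid and length.
#' @return An object of class `fused_tf`: list with `magnitude`,
#'   `n_channels`, `n_freqs`, `grid`.
#' @export
fuse_channels <- function(scalograms) {
  stopifnot(length(scalograms) >= 1,
            all(vapply(scalograms, inherits, TRUE, "scalogram")))
  f0 <- scalograms[[1]]$grid$frequencies
  nc0 <- ncol(scalograms[[1]]$magnitude)
  for (s in scalograms[-1]) {
    if (!identical(s$grid$frequencies, f0) || ncol(s$magnitude) != nc0) {
      stop("scalograms must share frequency grid and sample count", call. = FALSE)
    }
  }
  structure(
    list(magnitude = do.call(rbind, lapply(scalograms, `[[`, "magnitude")),
         n_channels = length(scalograms), n_freqs = length(f0),
         grid = scalograms[[1]]$grid),
    class = "fused_tf"
  )
}

# Bilinear resize of a matrix via interpolation matrices (align-corners).
resize_bilinear <- function(m, out_h, out_w) {
  interp_matrix <- function(n_in, n_out) {
    if (n_out == 1 || n_in == 1) {
      return(matrix(1 / n_in, nrow = n_out, ncol = n_in))
    }
    src <- (seq_len(n_out) - 1) * (n_in - 1) / (n_out - 1) + 1
    lo <- pmin(floor(src), n_in - 1)
    w <- src - lo
    a <- matrix(0, n_out, n_in)
    a[cbind(seq_len(n_out), lo)] <- 1 - w
    a[cbind(seq_len(n_out), lo + 1)] <- a[cbind(seq_len(n_out), lo + 1)] + w
    a
  }
  interp_matrix(nrow(m), out_h) %*% m %*% t(interp_matrix(ncol(m), out_w))
}

# Classic "jet" ramp evaluated at v in [0, 1]; returns [n x 3] in [0, 1].
jet_rgb <- function(v) {
  clamp <- function(z) pmin(pmax(z, 0), 1)
  cbind(clamp(1.5 - abs(4 * v - 3)),
        clamp(1.5 - abs(4 * v - 2)),
        clamp(1.5 - abs(4 * v - 1)))
}

gray_rgb <- function(v) cbind(v, v, v)

#' Render a fused time-frequency matrix as a fixed-size RGB image
#'
#' The scalar magnitude field is bilinearly resized to `size x size`,
#' normalized by a monotone map (per-image min-max, optionally after a
#' `log1p` transform), and colorized through a colormap, yielding the
#' `[size x size x 3]` array fed to the convolutional feature extractor.
#' A constant (zero-range) input maps to the colormap midpoint, except the
#' all-zero input which maps to the colormap's lowest color.
#'
#' @param fused A [fuse_channels()] result (or any `fused_tf`).
#' @param size Output height = width in pixels (224 by default).
#' @param norm `"minmax"` or `"log"` (log1p then min-max).
#' @param colormap `"jet"` or `"gray"`.
#' @return An object of class `rgb_image`: list with `pixels`
#'   (`[size x size x 3]`, values in \[0, 1\]), `size`, `norm`, `colormap`.
#' @export
render_rgb <- function(fused, size = 224, norm = c("minmax", "log"),
                       colormap = c("jet", "gray")) {
  stopifnot(inherits(fused, "fused_tf"), size >= 2)
  norm <- match.arg(norm)
  colormap <- match.arg(colormap)
  m <- fused$magnitude
  if (length(m) == 0) stop("empty fused representation", call. = FALSE)
  if (norm == "log") m <- log1p(m)
  r <- resize_bilinear(m, size, size)
  rng <- range(r)
  v <- if (rng[2] > rng[1]) {
    (r - rng[1]) / (rng[2] - rng[1])
  } else if (rng[1] == 0) {
    matrix(0, size, size) # all-zero input: lowest color
  } else {
    matrix(0.5, size, size) # constant nonzero: defined midpoint
  }
  cm <- switch(colormap, jet = jet_rgb, gray = gray_rgb)
  rgb <- cm(as.vector(v))
  structure(
    list(pixels = array(rgb, dim = c(size, size, 3)),
         size = size, norm = norm, colormap = colormap),
    class = "rgb_image"
  )
}

#' Full representation of one trial: CWT per channel, fuse, render
#'
#' @param trial A `semg_trial`.
#' @param grid A [frequency_grid()] matching the trial's sampling rate.
#' @param size,norm,colormap Passed to [render_rgb()].
#' @return An `rgb_image`.
#' @export
trial_to_image <- function(trial, grid, size = 224, norm = "minmax",
                           colormap = "jet") {
  stopifnot(inherits(trial, "semg_trial"))
  fs <- trial$acq$sampling_rate
  sc <- lapply(seq_len(nrow(trial$data)), function(ch) {
    mdtfr(trial$data[ch, ], fs, grid, channel_id = ch)
  })
  render_rgb(fuse_channels(sc), size = size, norm = norm, colormap = colormap)
}

#' @export
print.scalogram <- function(x, ...) {
  cat("<scalogram>", nrow(x$magnitude), "freqs x", ncol(x$magnitude),
      "samples,", x$grid$f_lo, "-", x$grid$f_hi, "Hz\n")
  invisible(x)
}

#' @export
print.fused_tf <- function(x, ...) {
  cat("<fused_tf>", x$n_channels, "channels x", x$n_freqs, "freqs =",
      nrow(x$magnitude), "rows x", ncol(x$magnitude), "samples\n")
  invisible(x)
}

#' @export
print.rgb_image <- function(x, ...) {
  cat("<rgb_image>", x$size, "x", x$size, "x 3,", x$norm, "norm,",
      x$colormap, "colormap\n")
  invisible(x)
}
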