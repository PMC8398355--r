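# Synthetic multichannel sEMG: amplitude-modulated band-limited Gaussian noise
# per channel, plus powerline / drift / baseline noise components.

# Deterministic sub-seed derivation; result stays below 2^31 - 1.
derive_seed <- function(seed, ...) {
  parts <- c(seed, ...)
  s <- 0
  for (p in parts) s <- (s * 69069 + as.numeric(p) + 1) %% 2147483647
  as.integer(s)
}

# Run fn with a private RNG stream so callers' RNG state is untouched.
with_seed <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Default per-class activation profiles
#'
#' Builds `n_classes` pairwise-distinct activation profiles. Each class gets
#' its own per-channel gain pattern and per-channel carrier band; bands are
#' placed inside 50--150 Hz, where most sEMG spectral energy concentrates,
#' and always within the 6--500 Hz functional band. The construction is
#' deterministic for a fixed seed.
#'
#' Gains combine a structured on/off pattern (so classes differ strongly in
#' which muscles are active) with continuous jitter (so no two classes are
#' identical even when patterns repeat).
#'
#' @param n_classes Number of movement classes (>= 2).
#' @param n_channels Number of channels (>= 1).
#' @param seed Integer seed.
#' @return List of `n_classes` [activation_profile()] objects.
#' @examples
#' profs <- default_profiles(12, 4, seed = 0)
#' profs[[1]]
#' @export
default_profiles <- function(n_classes, n_channels, seed = 0) {
  if (n_channels < 1) stop("n_channels must be >= 1", call. = FALSE)
  if (n_classes < 2) stop("n_classes must be >= 2", call. = FALSE)
  with_seed(derive_seed(seed, 7001), function() {
    lapply(seq_len(n_classes), function(cl) {
      # structured on/off muscle pattern: rotate a strong/weak mask per class
      mask <- ((seq_len(n_channels) + cl) %% min(n_channels + 1, 4)) < 2
      gains <- ifelse(mask, 1.5, 0.35) * stats::runif(n_channels, 0.8, 1.2)
      center <- stats::runif(n_channels, 70, 130)
      half <- stats::runif(n_channels, 12, 22)
      bands <- cbind(pmax(center - half, 50), pmin(center + half, 150))
      activation_profile(gains = gains, bands = bands)
    })
  })
}

# Band-limited unit-RMS Gaussian noise via frequency-domain shaping.
band_limited_noise <- function(n, fs, f_lo, f_hi, edge = 2) {
  z <- stats::rnorm(n)
  fz <- stats::fft(z)
  freqs <- (seq_len(n) - 1) * fs / n
  freqs <- pmin(freqs, fs - freqs) # two-sided
  # raised-cosine band edges of width `edge` Hz
  w <- rep(0, n)
  inside <- freqs >= f_lo & freqs <= f_hi
  w[inside] <- 1
  lo_ramp <- freqs >= (f_lo - edge) & freqs < f_lo
  w[lo_ramp] <- 0.5 * (1 + cos(pi * (f_lo - freqs[lo_ramp]) / edge))
  hi_ramp <- freqs > f_hi & freqs <= (f_hi + edge)
  w[hi_ramp] <- 0.5 * (1 + cos(pi * (freqs[hi_ramp] - f_hi) / edge))
  x <- Re(stats::fft(fz * w, inverse = TRUE)) / n
  r <- sqrt(mean(x^2))
  if (r > 0) x / r else x
}

# Ramp-plateau-ramp contraction envelope with raised-cosine ramps.
contraction_envelope <- function(n, onset, offset, ramp_frac = 0.1) {
  t <- (seq_len(n) - 0.5) / n
  env <- rep(0, n)
  ramp <- ramp_frac * (offset - onset)
  up <- t >= onset & t < onset + ramp
  plateau <- t >= onset + ramp & t <= offset - ramp
  down <- t > offset - ramp & t <= offset
  env[up] <- 0.5 * (1 - cos(pi * (t[up] - onset) / ramp))
  env[plateau] <- 1
  env[down] <- 0.5 * (1 - cos(pi * (offset - t[down]) / ramp))
  env
}

#' Generate one synthetic sEMG trial
#'
#' Each channel is band-limited Gaussian noise (the profile's carrier band)
#' amplitude-modulated by a smooth ramp-plateau-ramp contraction envelope and
#' scaled by the profile gain times `subject_scale`. Three noise components
#' are then added per channel: white baseline noise, a 50 Hz powerline
#' sinusoid with random phase, and sub-6 Hz motion-artifact drift.
#'
#' @param profile [activation_profile()] for the movement class.
#' @param class_id,subject_id Integer labels stored with the trial.
#' @param acq [acquisition_spec()].
#' @param noise [noise_spec()].
#' @param seed Integer seed; the trial is reproducible given all arguments.
#' @param subject_scale Multiplicative per-subject gain factor(s); scalar or
#'   one value per channel.
#' @return An object of class `semg_trial`: list with `data`
#'   (`[n_channels x samples]` matrix), `class_id`, `subject_id`, `acq`,
#'   `preprocessed` flag.
#' @examples
#' acq <- acquisition_spec(duration = 1)
#' tr <- generate_trial(default_profiles(12, 4)[[1]], 1, 1, acq, noise_spec(), seed = 1)
#' dim(tr$data) # 4 x 2048
#' @export
generate_trial <- function(profile, class_id, subject_id, acq, noise,
                           seed = 0, subject_scale = 1) {
  stopifnot(inherits(profile, "activation_profile"),
            inherits(acq, "acquisition_spec"),
            inherits(noise, "noise_spec"))
  nch <- acq$n_channels
  if (length(profile$gains) != nch) {
    stop("profile channel count does not match acquisition spec", call. = FALSE)
  }
  scale <- rep_len(subject_scale, nch)
  n <- samples_per_trial(acq)
  fs <- acq$sampling_rate
  t <- (seq_len(n) - 1) / fs
  env <- contraction_envelope(n, profile$onset, profile$offset)
  data <- with_seed(derive_seed(seed, subject_id, class_id, 991), function() {
    m <- matrix(0, nrow = nch, ncol = n)
    for (ch in seq_len(nch)) {
      x <- rep(0, n)
      if (profile$gains[ch] > 0) {
        carrier <- band_limited_noise(n, fs, profile$bands[ch, 1], profile$bands[ch, 2])
        x <- profile$gains[ch] * scale[ch] * env * carrier
      }
      if (noise$baseline_rms > 0) x <- x + stats::rnorm(n, sd = noise$baseline_rms)
      if (noise$powerline_amplitude > 0) {
        x <- x + noise$powerline_amplitude *
          sin(2 * pi * noise$powerline_freq * t + stats::runif(1, 0, 2 * pi))
      }
      if (noise$drift_amplitude > 0) {
        d <- band_limited_noise(n, fs, 0.2, 4, edge = 0.2)
        x <- x + noise$drift_amplitude * d
      }
      m[ch, ] <- x
    }
    m
  })
  structure(
    list(data = data, class_id = as.integer(class_id),
         subject_id = as.integer(subject_id), acq = acq, preprocessed = FALSE),
    class = "semg_trial"
  )
}

#' @export
print.semg_trial <- function(x, ...) {
  cat("<semg_trial> class", x$class_id, "subject", x$subject_id, "-",
      nrow(x$data), "ch x", ncol(x$data), "samples",
      if (isTRUE(x$preprocessed)) "(preprocessed)" else "(raw)", "\n")
  invisible(x)
}

# Split a total count as evenly as possible over n cells (first cells get +1).
distribute_count <- function(total, n) {
  base <- total %/% n
  counts <- rep(base, n)
  extra <- total - base * n
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1
  counts
}

#' Generate a full synthetic sEMG dataset
#'
#' Generates trials for every (subject, class) cell. Per-subject variability
#' is modelled as multiplicative log-normal gain jitter drawn once per subject
#' and channel, making subject-wise train/test splits non-trivial.
#'
#' @param acq [acquisition_spec()].
#' @param noise [noise_spec()].
#' @param seed Integer master seed; all trial seeds derive from it and are
#'   recorded in the manifest.
#' @param profiles Optional list of per-class [activation_profile()]s;
#'   defaults to [default_profiles()] seeded from `seed`.
#' @param subject_sigma Log-normal sigma of per-subject gain jitter.
#' @param trials_per_class_total Optional total trial count per class for the
#'   whole corpus; when given it overrides
#'   `acq$trials_per_class_per_subject` and is distributed as evenly as
#'   possible across subjects (some subjects get one more repetition), so
#'   uneven corpus sizes such as 47 trials per class are expressible.
#' @return An object of class `semg_dataset`: list with `trials` (a tibble
#'   with columns subject, class, trial, seed, data), `acq`, `noise`,
#'   `profiles`, `subject_scales`, `seed`.
#' @examples
#' acq <- acquisition_spec(duration = 0.25, n_classes = 3, n_subjects = 2,
#'                         trials_per_class_per_subject = 2)
#' ds <- generate_dataset(acq, noise_spec(), seed = 1)
#' nrow(ds$trials) # 12
#' @export
generate_dataset <- function(acq, noise, seed = 0, profiles = NULL,
                             subject_sigma = 0.2,
                             trials_per_class_total = NULL) {
  stopifnot(inherits(acq, "acquisition_spec"), inherits(noise, "noise_spec"))
  if (is.null(profiles)) {
    profiles <- default_profiles(acq$n_classes, acq$n_channels, seed = seed)
  }
  stopifnot(length(profiles) == acq$n_classes)
  subject_scales <- with_seed(derive_seed(seed, 5003), function() {
    matrix(stats::rlnorm(acq$n_subjects * acq$n_channels, 0, subject_sigma),
           nrow = acq$n_subjects)
  })
  per_subject <- if (is.null(trials_per_class_total)) {
    rep(acq$trials_per_class_per_subject, acq$n_subjects)
  } else {
    distribute_count(trials_per_class_total, acq$n_subjects)
  }
  rows <- list()
  i <- 0
  for (s in seq_len(acq$n_subjects)) {
    for (cl in seq_len(acq$n_classes)) {
      for (k in seq_len(per_subject[s])) {
        i <- i + 1
        trial_seed <- derive_seed(seed, s, cl, k)
        tr <- generate_trial(profiles[[cl]], cl, s, acq, noise,
                             seed = trial_seed,
                             subject_scale = subject_scales[s, ])
        rows[[i]] <- tibble::tibble(
          subject = s, class = cl, trial = k, seed = trial_seed,
          data = list(tr$data)
        )
      }
    }
  }
  structure(
    list(trials = dplyr::bind_rows(rows), acq = acq, noise = noise,
         profiles = profiles, subject_scales = subject_scales,
         seed = seed, preprocessed = FALSE),
    class = "semg_dataset"
  )
}

#' @export
print.semg_dataset <- function(x, ...) {
  cat("<semg_dataset>", nrow(x$trials), "trials:",
      x$acq$n_subjects, "subjects x", x$acq$n_classes, "classes,",
      x$acq$n_channels, "ch x", samples_per_trial(x$acq), "samples",
      if (isTRUE(x$preprocessed)) "(preprocessed)\n" else "(raw)\n")
  invisible(x)
}

#' Export one trial as CSV (one column per channel)
#'
#' Columns are headed `CH1..CHn`, one row per sample.
#'
#' @param trial A `semg_trial` or a `[channels x samples]` matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  m <- if (inherits(trial, "semg_trial")) trial$data else trial
  df <- as.data.frame(t(m))
  names(df) <- paste0("CH", seq_len(nrow(m)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a dataset to a directory of CSV trials plus a JSON manifest
#'
#' Layout: `subject_<s>/class_<c>/trial_<k>.csv` under `dir`, with
#' `manifest.json` recording the acquisition and noise specs, the master and
#' per-trial seeds, and the file inventory. The writer is deterministic:
#' identical datasets produce byte-identical payloads.
#'
#' @param dataset A `semg_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "semg_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- dataset$trials
  files <- character(nrow(tr))
  for (i in seq_len(nrow(tr))) {
    sub <- file.path(dir, sprintf("subject_%d/class_%d", tr$subject[i], tr$class[i]))
    dir.create(sub, recursive = TRUE, showWarnings = FALSE)
    files[i] <- file.path(sub, sprintf("trial_%d.csv", tr$trial[i]))
    write_trial_csv(tr$data[[i]], files[i])
  }
  manifest <- list(
    acquisition = unclass(dataset$acq),
    noise = unclass(dataset$noise),
    master_seed = dataset$seed,
    preprocessed = isTRUE(dataset$preprocessed),
    trials = data.frame(
      subject = tr$subject, class = tr$class, trial = tr$trial,
      seed = tr$seed, file = sub("^/", "", substring(files, nchar(dir) + 2))
    )
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a dataset written by [write_dataset()]
#'
#' @param dir Directory containing `manifest.json`.
#' @return A `semg_dataset` (profiles and subject scales are not stored in
#'   the exchange format and come back `NULL`).
#' @export
read_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  a <- manifest$acquisition
  acq <- acquisition_spec(a$sampling_rate, a$duration, a$n_channels,
                          a$n_classes, a$trials_per_class_per_subject,
                          a$n_subjects)
  nz <- manifest$noise
  noise <- noise_spec(nz$baseline_rms, nz$powerline_amplitude,
                      nz$drift_amplitude, nz$powerline_freq)
  inv <- manifest$trials
  data <- lapply(inv$file, function(f) {
    t(as.matrix(utils::read.csv(file.path(dir, f))))
  })
  structure(
    list(
      trials = tibble::tibble(subject = inv$subject, class = inv$class,
                              trial = inv$trial, seed = inv$seed, data = data),
      acq = acq, noise = noise, profiles = NULL, subject_scales = NULL,
      seed = manifest$master_seed,
      preprocessed = isTRUE(manifest$preprocessed)
    ),
    class = "semg_dataset"
  )
}
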