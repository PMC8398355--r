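test_that("default profiles are distinct, deterministic and band-limited", {
  profs <- default_profiles(12, 4, seed = 0)
  expect_length(profs, 12)
  for (i in 1:11) {
    for (j in (i + 1):12) {
      expect_false(identical(profs[[i]]$gains, profs[[j]]$gains) &&
                     identical(profs[[i]]$bands, profs[[j]]$bands))
    }
  }
  expect_identical(default_profiles(2, 1, seed = 0),
                   default_profiles(2, 1, seed = 0))
  for (p in profs) {
    expect_true(all(p$bands >= 6) && all(p$bands <= 500))
    expect_true(all(p$bands[, 1] < p$bands[, 2]))
  }
  expect_error(default_profiles(12, 0, seed = 0), "n_channels")
})

test_that("trial generation matches the acquisition protocol", {
  acq <- acquisition_spec() # 2048 Hz x 5 s
  expect_identical(samples_per_trial(acq), 10240L)
  tr <- generate_trial(default_profiles(12, 4, 1)[[1]], 3, 2, acq,
                       noise_spec(), seed = 9)
  expect_identical(dim(tr$data), c(4L, 10240L))
  expect_true(all(is.finite(tr$data)))
  expect_identical(tr$class_id, 3L)
  tr2 <- generate_trial(default_profiles(12, 4, 1)[[1]], 3, 2, acq,
                        noise_spec(), seed = 9)
  expect_identical(tr$data, tr2$data)
})

test_that("with all gains zero only the configured noise floor remains", {
  acq <- acquisition_spec(duration = 1)
  prof <- activation_profile(gains = rep(0, 4),
                             bands = matrix(rep(c(80, 120), each = 4), ncol = 2))
  sigma <- 0.3
  tr <- generate_trial(prof, 1, 1, acq,
                       noise_spec(baseline_rms = sigma,
                                  powerline_amplitude = 0,
                                  drift_amplitude = 0), seed = 3)
  rms <- sqrt(rowMeans(tr$data^2))
  expect_true(all(abs(rms - sigma) / sigma < 0.1))
})

test_that("channel spectra peak inside the profile carrier band", {
  acq <- acquisition_spec(duration = 2)
  prof <- activation_profile(gains = c(5, 0, 0, 0),
                             bands = matrix(rep(c(80, 120), each = 4),
                                            ncol = 2, byrow = FALSE))
  tr <- generate_trial(prof, 1, 1, acq,
                       noise_spec(baseline_rms = 0.01,
                                  powerline_amplitude = 0,
                                  drift_amplitude = 0), seed = 5)
  pk <- welch_peak_freq(tr$data[1, ], acq$sampling_rate)
  expect_gte(pk, 78)
  expect_lte(pk, 122)
})

test_that("spectral placement holds across generated profiles", {
  acq <- acquisition_spec(duration = 1, n_classes = 6)
  profs <- default_profiles(6, 4, seed = 11)
  quiet <- noise_spec(baseline_rms = 0.01, powerline_amplitude = 0,
                      drift_amplitude = 0)
  for (cl in seq_along(profs)) {
    tr <- generate_trial(profs[[cl]], cl, 1, acq, quiet, seed = cl)
    for (ch in 1:4) {
      if (profs[[cl]]$gains[ch] > 0.5) {
        pk <- welch_peak_freq(tr$data[ch, ], acq$sampling_rate)
        expect_gte(pk, profs[[cl]]$bands[ch, 1] - 2)
        expect_lte(pk, profs[[cl]]$bands[ch, 2] + 2)
      }
    }
  }
})

test_that("dataset generation populates every cell with the requested counts", {
  acq <- acquisition_spec(duration = 0.25, n_classes = 12, n_subjects = 2,
                          trials_per_class_per_subject = 3)
  ds <- generate_dataset(acq, noise_spec(), seed = 2)
  expect_identical(nrow(ds$trials), 72L)
  cells <- dplyr::count(ds$trials, subject, class)
  expect_identical(nrow(cells), 24L)
  expect_true(all(cells$n == 3))
})

test_that("a 47-trials-per-class corpus is expressible with 14 subjects", {
  acq <- acquisition_spec(duration = 0.05, n_classes = 12, n_subjects = 14)
  ds <- generate_dataset(acq, noise_spec(), seed = 3,
                         trials_per_class_total = 47)
  expect_identical(nrow(ds$trials), 47L * 12L)
  per_class <- dplyr::count(ds$trials, class)
  expect_true(all(per_class$n == 47))
})

test_that("dataset writing is byte-deterministic and round-trips", {
  acq <- acquisition_spec(duration = 0.1, n_classes = 2, n_subjects = 2,
                          trials_per_class_per_subject = 1)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_dataset(generate_dataset(acq, noise_spec(), seed = 8), d1)
  write_dataset(generate_dataset(acq, noise_spec(), seed = 8), d2)
  f1 <- sort(list.files(d1, recursive = TRUE))
  expect_identical(f1, sort(list.files(d2, recursive = TRUE)))
  for (f in f1) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e6),
                     readBin(file.path(d2, f), "raw", 1e6))
  }
  back <- read_dataset(d1)
  orig <- generate_dataset(acq, noise_spec(), seed = 8)
  expect_equal(back$trials$data[[1]], unname(orig$trials$data[[1]]),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_identical(back$trials$class, orig$trials$class)
})

test_that("clean trials are linearly separable from band-power features", {
  skip_if_not_installed("MASS")
  acq <- acquisition_spec(duration = 1, n_subjects = 1,
                          trials_per_class_per_subject = 10)
  quiet <- noise_spec(baseline_rms = 0.02, powerline_amplitude = 0,
                      drift_amplitude = 0)
  ds <- generate_dataset(acq, quiet, seed = 21)
  bands <- list(c(50, 80), c(80, 110), c(110, 150))
  feats <- t(vapply(ds$trials$data, function(m) {
    unlist(lapply(seq_len(nrow(m)), function(ch) {
      vapply(bands, function(b) {
        log(band_power(m[ch, ], acq$sampling_rate, b[1], b[2]))
      }, 0)
    }))
  }, numeric(12)))
  cls <- factor(ds$trials$class)
  fit <- MASS::lda(feats, grouping = cls)
  acc <- mean(predict(fit, feats)$class == cls)
  expect_gt(acc, 0.9)
})
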