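fs <- 2048

test_that("frequency grid covers the functional band with matched scales", {
  g <- make_grid(6, 500, 1, fs)
  expect_length(g$frequencies, 495)
  expect_true(all(diff(g$frequencies) > 0))
  expect_true(all(diff(g$scales) < 0))
  # numeric inversion oracle: the wavelet response at scale s_i peaks at f_i
  omega0 <- g$wavelet$omega0
  for (i in c(1, 50, 250, 495)) {
    s <- g$scales[i]
    f_fine <- seq(1, 520, by = 0.01)
    resp <- exp(-0.5 * (s * 2 * pi * f_fine / fs - omega0)^2)
    expect_lt(abs(f_fine[which.max(resp)] - g$frequencies[i]), 0.5)
  }
  expect_error(make_grid(6, 500, 1, 800), "Nyquist")
})

test_that("scalogram localizes pure tones and is linear", {
  g <- make_grid(6, 500, 1, fs)
  t2 <- (0:(fs * 2 - 1)) / fs
  for (f0 in c(20, 100, 400)) {
    s <- mdtfr(sin(2 * pi * f0 * t2), fs, g)
    peak_row <- which.max(rowMeans(s$magnitude))
    expect_lte(abs(peak_row - which.min(abs(g$frequencies - f0))), 2)
  }
  # energy concentration: >= 50% of scalogram energy within +-5 rows of the
  # tone, on grids whose spacing resolves the wavelet's constant-Q bandwidth
  # (sigma_f = f / omega0 grows with frequency, so the grid must too)
  for (case in list(list(f0 = 20, step = 1), list(f0 = 100, step = 8),
                    list(f0 = 200, step = 8))) {
    gc <- make_grid(6, 500, case$step, fs)
    s <- mdtfr(sin(2 * pi * case$f0 * t2), fs, gc)
    peak_row <- which.max(rowMeans(s$magnitude))
    rows <- pmax(1, peak_row - 5):pmin(nrow(s$magnitude), peak_row + 5)
    expect_gte(sum(s$magnitude[rows, ]^2) / sum(s$magnitude^2), 0.5)
  }
  x <- sin(2 * pi * 100 * t2)
  expect_equal(mdtfr(2.5 * x, fs, g)$magnitude,
               2.5 * mdtfr(x, fs, g)$magnitude, tolerance = 1e-10)
  z <- mdtfr(rep(0, 1024), fs, g)
  expect_equal(max(z$magnitude), 0)
  expect_error(mdtfr(numeric(0), fs, g), "empty")
})

test_that("a rising chirp produces a monotone ridge", {
  g <- make_grid(6, 500, 2, fs)
  t2 <- (0:(fs * 2 - 1)) / fs
  # linear chirp 20 -> 200 Hz over 2 s
  x <- sin(2 * pi * (20 * t2 + (200 - 20) / (2 * 2) * t2^2))
  s <- mdtfr(x, fs, g)
  interior <- seq(fs %/% 4, length(t2) - fs %/% 4)
  ridge <- apply(s$magnitude[, interior], 2, which.max)
  expect_gt(cor(ridge, seq_along(ridge), method = "spearman"), 0.95)
})

test_that("time shifts translate scalogram columns", {
  g <- make_grid(20, 300, 4, fs)
  set.seed(9)
  burst <- rnorm(256)
  delta <- 100
  x1 <- c(rep(0, 1024), burst, rep(0, 1024))
  x2 <- c(rep(0, 1024 + delta), burst, rep(0, 1024 - delta))
  s1 <- mdtfr(x1, fs, g)$magnitude
  s2 <- mdtfr(x2, fs, g)$magnitude
  interior <- 600:1800 # away from the edges
  expect_equal(s2[, interior + delta], s1[, interior], tolerance = 1e-6)
})

test_that("channel fusion stacks blocks in order, bit for bit", {
  g <- make_grid(6, 500, 1, fs)
  set.seed(2)
  scs <- lapply(1:4, function(ch) mdtfr(rnorm(512), fs, g, channel_id = ch))
  fused <- fuse_channels(scs)
  expect_identical(dim(fused$magnitude), c(1980L, 512L))
  expect_identical(fused$magnitude[1:495, ], scs[[1]]$magnitude)
  expect_identical(fused$magnitude[496:990, ], scs[[2]]$magnitude)
  perm <- fuse_channels(scs[c(3, 1, 4, 2)])
  expect_identical(perm$magnitude[1:495, ], scs[[3]]$magnitude)
  g2 <- make_grid(6, 400, 1, fs)
  bad <- mdtfr(rnorm(512), fs, g2)
  expect_error(fuse_channels(list(scs[[1]], bad)), "share")
})

test_that("RGB rendering has fixed shape and min-max invariances", {
  g <- make_grid(6, 500, 5, fs)
  set.seed(3)
  scs <- lapply(1:4, function(ch) mdtfr(rnorm(2048), fs, g))
  fused <- fuse_channels(scs)
  img <- render_rgb(fused, size = 224)
  expect_identical(dim(img$pixels), c(224L, 224L, 3L))
  expect_true(all(img$pixels >= 0 & img$pixels <= 1))
  # scale invariance of min-max normalization
  fused2 <- fused
  fused2$magnitude <- fused$magnitude * 7.3
  expect_equal(render_rgb(fused2, size = 64)$pixels,
               render_rgb(fused, size = 64)$pixels, tolerance = 1e-12)
  # all-zero input renders the colormap's lowest color everywhere
  fused0 <- fused
  fused0$magnitude[] <- 0
  img0 <- render_rgb(fused0, size = 32)
  expect_identical(dim(unique(matrix(img0$pixels, ncol = 3))), c(1L, 3L))
  expect_identical(as.vector(img0$pixels[1, 1, ]),
                   as.vector(render_rgb(fused, 32)$pixels[1, 1, ] * 0 +
                               semgfusion:::jet_rgb(0)[1, ]))
  # constant nonzero input maps to the colormap midpoint
  fusedc <- fused
  fusedc$magnitude[] <- 4.2
  imgc <- render_rgb(fusedc, size = 32)
  expect_equal(as.vector(imgc$pixels[3, 3, ]),
               as.vector(semgfusion:::jet_rgb(0.5)[1, ]))
})

test_that("the whole representation is deterministic", {
  acq <- acquisition_spec(duration = 0.5)
  tr <- generate_trial(default_profiles(12, 4, 1)[[2]], 2, 1, acq,
                       noise_spec(), seed = 4)
  g <- make_grid(6, 500, 10, fs)
  i1 <- trial_to_image(tr, g, size = 64)
  i2 <- trial_to_image(tr, g, size = 64)
  expect_identical(i1$pixels, i2$pixels)
})
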