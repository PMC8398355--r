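scaled_cfg <- function() {
  mffn_config(input_size = 64, stem_filters = 24, block_sizes = c(3, 6),
              growth = 12)
}

test_that("the shape plan reproduces the full-scale layer table", {
  plan <- shape_plan(mffn_config())
  get <- function(stage) unlist(plan[plan$stage == stage, c("height", "width", "channels")])
  expect_equal(unname(get("convolution")), c(112, 112, 64))
  expect_equal(unname(get("pooling")), c(56, 56, 64))
  expect_equal(unname(get("dense_block_1")), c(56, 56, 256))
  expect_equal(unname(get("transition_1")), c(28, 28, 128))
  expect_equal(unname(get("dense_block_2")), c(28, 28, 512))
  expect_equal(unname(get("transition_2")), c(14, 14, 256))
  expect_equal(unname(get("flatten"))[3], 50176)
  expect_error(shape_plan(mffn_config(input_size = 225)), "even spatial")
})

test_that("realized forward shapes equal the symbolic plan", {
  cfgs <- list(scaled_cfg(),
               mffn_config(input_size = 32, stem_filters = 8,
                           block_sizes = c(2, 2), growth = 4,
                           bottleneck_factor = 2),
               mffn_config(input_size = 48, stem_filters = 6,
                           block_sizes = c(1, 3), growth = 6,
                           compression = 0.75))
  for (cfg in cfgs) {
    plan <- shape_plan(cfg)
    m <- build_mffn(cfg, seed = 2)
    x <- array(stats::runif(cfg$input_size^2 * 3 * 2),
               c(cfg$input_size, cfg$input_size, 3, 2))
    y <- mffn_forward(m, x)$y
    final <- plan[plan$stage == sprintf("transition_%d", length(cfg$block_sizes)), ]
    expect_equal(dim(y), c(final$height, final$width, final$channels, 2))
  }
})

test_that("forward passes are deterministic in evaluation mode", {
  m <- build_mffn(scaled_cfg(), seed = 7)
  x <- array(stats::runif(64 * 64 * 3), c(64, 64, 3, 1))
  expect_identical(mffn_forward(m, x)$y, mffn_forward(m, x)$y)
  m2 <- build_mffn(scaled_cfg(), seed = 7)
  expect_identical(mffn_forward(m, x)$y, mffn_forward(m2, x)$y)
})

test_that("dense blocks grow channels by L * k and wire all connections", {
  x1 <- array(stats::rnorm(8 * 8 * 64), c(8, 8, 64, 1))
  y1 <- dense_block_forward(x1, n_layers = 6, growth = 32)
  expect_equal(dim(y1)[3], 256) # 64 + 6*32
  x2 <- array(stats::rnorm(8 * 8 * 128), c(8, 8, 128, 1))
  y2 <- dense_block_forward(x2, n_layers = 12, growth = 32)
  expect_equal(dim(y2)[3], 512) # 128 + 12*32
  expect_identical(dense_block_forward(x1, n_layers = 0), x1)
  for (L in 1:6) {
    expect_equal(count_dense_connections(L), L * (L + 1) / 2)
  }
})

test_that("dense layer j consumes c_in + (j-1)k channels", {
  m <- build_mffn(scaled_cfg(), seed = 1)
  for (b in seq_along(m$blocks)) {
    blk <- m$blocks[[b]]
    for (j in seq_along(blk$layers)) {
      expect_equal(blk$layers[[j]]$bn1$c, blk$c_in + (j - 1) * blk$growth)
      expect_equal(nrow(blk$layers[[j]]$conv1$W), blk$c_in + (j - 1) * blk$growth)
    }
  }
})

test_that("transition layers compress channels and halve spatial size", {
  x <- array(stats::rnorm(56 * 56 * 256 / 16), c(14, 14, 16, 1))
  y <- transition_forward(x, compression = 0.5)
  expect_equal(dim(y), c(7, 7, 8, 1))
  y2 <- transition_forward(array(stats::rnorm(4 * 4 * 8), c(4, 4, 8, 1)),
                           compression = 1)
  expect_equal(dim(y2), c(2, 2, 8, 1))
  expect_error(transition_forward(array(0, c(5, 5, 4, 1))), "even spatial")
})

test_that("feature extraction returns the flattened extraction point", {
  cfg <- scaled_cfg()
  m <- build_mffn(cfg, seed = 3)
  d_flat <- utils::tail(shape_plan(cfg)$channels, 1)
  img <- array(stats::runif(64 * 64 * 3), c(64, 64, 3))
  fm <- extract_features(m, img)
  expect_s3_class(fm, "feature_map")
  expect_length(fm$flat, d_flat)
  expect_identical(fm$flat, as.vector(fm$map))
  # batch preserves order
  batch <- array(stats::runif(64 * 64 * 3 * 3), c(64, 64, 3, 3))
  fms <- extract_features(m, batch, batch_size = 2)
  expect_length(fms, 3)
  one <- extract_features(m, batch[, , , 2, drop = TRUE])
  expect_equal(fms[[2]]$flat, one$flat, tolerance = 1e-12)
  expect_error(extract_features(m, array(0, c(32, 32, 3))), "shape")
})

test_that("a zero image yields zero features in a BN-identity model", {
  cfg <- mffn_config(input_size = 16, stem_filters = 4, stem_kernel = 3,
                     stem_stride = 2, stem_pad = 1, block_sizes = c(1, 1),
                     growth = 2, bottleneck_factor = 2)
  m <- build_mffn(cfg, seed = 5)
  # convs are bias-free; with running stats at (0, 1) and beta = 0 the whole
  # composite is linear through zero
  fm <- extract_features(m, array(0, c(16, 16, 3)))
  expect_equal(max(abs(fm$flat)), 0)
})

test_that("channel means match a brute-force spatial loop", {
  set.seed(10)
  fm <- array(stats::rnorm(5 * 5 * 7), c(5, 5, 7))
  prof <- channel_mean_profile(fm)
  oracle <- numeric(7)
  for (c in 1:7) {
    s <- 0
    for (i in 1:5) for (j in 1:5) s <- s + fm[i, j, c]
    oracle[c] <- s / 25
  }
  expect_equal(prof, oracle, tolerance = 1e-12)
  ones <- array(1, c(3, 3, 4))
  expect_equal(channel_mean_profile(ones), rep(1, 4))
  mix <- array(0, c(3, 3, 4)); mix[, , 1] <- 2
  expect_equal(channel_mean_profile(mix), c(2, 0, 0, 0))
})

test_that("every dense-layer weight receives gradient after one step", {
  cfg <- mffn_config(input_size = 16, stem_filters = 4, stem_kernel = 3,
                     stem_stride = 2, stem_pad = 1, block_sizes = c(2, 2),
                     growth = 3, bottleneck_factor = 2)
  m <- build_mffn(cfg, seed = 6)
  set.seed(11)
  x <- array(stats::rnorm(16 * 16 * 3 * 4), c(16, 16, 3, 4))
  fw <- mffn_forward(m, x, train = TRUE)
  dy <- array(stats::rnorm(length(fw$y)), dim(fw$y))
  bw <- mffn_backward(fw$model, fw$caches, dy)
  for (b in seq_along(m$blocks)) {
    for (j in seq_along(m$blocks[[b]]$layers)) {
      g <- bw$grads$blocks[[b]]$layers[[j]]
      expect_gt(min(abs(range(g$conv1$W))), 0)
      expect_gt(min(abs(range(g$conv2$W))), 0)
      expect_true(any(g$bn1$gamma != 0) && any(g$bn2$gamma != 0))
    }
  }
  expect_true(any(bw$grads$stem$conv$W != 0))
  # and a training step actually changes the parameters
  upd <- semgfusion:::adam_apply(m, bw$grads, semgfusion:::adam_state(),
                                 lr = 1e-3)
  expect_false(identical(upd$model$blocks[[1]]$layers[[1]]$conv2$W,
                         m$blocks[[1]]$layers[[1]]$conv2$W))
})

test_that("analytic gradients match finite differences on a small net", {
  cfg <- mffn_config(input_size = 16, stem_filters = 4, stem_kernel = 3,
                     stem_stride = 2, stem_pad = 1, block_sizes = c(1, 1),
                     growth = 2, bottleneck_factor = 2)
  m <- build_mffn(cfg, seed = 3)
  set.seed(42)
  x <- array(stats::rnorm(16 * 16 * 3 * 4), c(16, 16, 3, 4))
  fw <- mffn_forward(m, x, train = TRUE)
  r <- array(stats::rnorm(length(fw$y)), dim(fw$y))
  bw <- mffn_backward(fw$model, fw$caches, r)
  loss <- function(model) sum(mffn_forward(model, x, train = TRUE)$y * r)
  eps <- 1e-5
  probe <- function(get, set, g) {
    i <- sample(length(g), 1)
    wp <- get(m); wp[i] <- wp[i] + eps
    wm <- get(m); wm[i] <- wm[i] - eps
    num <- (loss(set(m, wp)) - loss(set(m, wm))) / (2 * eps)
    expect_equal(g[i], num, tolerance = 1e-4)
  }
  probe(function(m) m$stem$conv$W,
        function(m, w) { m$stem$conv$W <- w; m },
        bw$grads$stem$conv$W)
  probe(function(m) m$blocks[[1]]$layers[[1]]$conv2$W,
        function(m, w) { m$blocks[[1]]$layers[[1]]$conv2$W <- w; m },
        bw$grads$blocks[[1]]$layers[[1]]$conv2$W)
  probe(function(m) m$transitions[[2]]$conv$W,
        function(m, w) { m$transitions[[2]]$conv$W <- w; m },
        bw$grads$transitions[[2]]$conv$W)
})
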