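test_that("hidden conditionals are the logistic of the affine map", {
  r <- rbm(3, 2, seed = 1)
  r$W[] <- 0
  out <- sample_h_given_v(r, c(1, 0, 1), seed = 1)
  expect_equal(as.vector(out$prob), c(0.5, 0.5))
  r$hbias <- c(50, -50)
  out2 <- sample_h_given_v(r, c(0, 0, 0), seed = 1)
  expect_equal(out2$prob[1], 1, tolerance = 1e-10)
  expect_equal(out2$prob[2], 0, tolerance = 1e-10)
  # hand-computed oracle on a random 3x2 machine
  r2 <- make_small_rbm(3, 2, seed = 3)
  v <- c(1, 1, 0)
  p <- sample_h_given_v(r2, v)$prob
  for (j in 1:2) {
    expect_equal(p[j], 1 / (1 + exp(-(sum(v * r2$W[, j]) + r2$hbias[j]))),
                 tolerance = 1e-12)
  }
})

test_that("hidden units are conditionally independent given v", {
  r <- make_small_rbm(4, 3, seed = 5)
  v <- c(1, 0, 1, 1)
  p_joint <- sample_h_given_v(r, v)$prob
  # each unit's conditional computed in isolation (sub-machine with only
  # that hidden unit) must agree
  for (j in 1:3) {
    rj <- rbm(4, 1)
    rj$W <- r$W[, j, drop = FALSE]
    rj$hbias <- r$hbias[j]
    rj$vbias <- r$vbias
    expect_equal(as.numeric(sample_h_given_v(rj, v)$prob), p_joint[j],
                 tolerance = 1e-12)
  }
})

test_that("exact log-likelihood is normalized and matches brute force", {
  r0 <- rbm(3, 2, seed = 1)
  r0$W[] <- 0
  expect_equal(exact_loglik(r0, matrix(c(1, 0, 1), 1)), -3 * log(2),
               tolerance = 1e-12)
  r <- make_small_rbm(3, 3, seed = 7)
  states <- semgfusion:::all_binary_states(3)
  total <- sum(vapply(seq_len(8), function(i) {
    exp(exact_loglik(r, states[i, , drop = FALSE]))
  }, 0))
  expect_equal(total, 1, tolerance = 1e-9)
  data <- states[c(1, 4, 6), ]
  expect_equal(exact_loglik(r, data), bruteforce_loglik(r, data),
               tolerance = 1e-9)
  expect_error(exact_loglik(rbm(15, 15), states), "enumerate")
})

test_that("contrastive divergence respects its contract", {
  r <- make_small_rbm(3, 2, seed = 9)
  batch <- matrix(c(1, 0, 1, 0, 1, 1), 2, 3, byrow = TRUE)
  set.seed(1)
  same <- cd_update(r, batch, k = 1, lr = 0)
  expect_identical(same$W, r$W)
  expect_identical(same$vbias, r$vbias)
  # duplicated rows average to the single-row update (mean-field CD is
  # deterministic given the batch)
  u1 <- cd_update(r, batch[1, , drop = FALSE], k = 1, lr = 0.1)
  u2 <- cd_update(r, batch[c(1, 1), ], k = 1, lr = 0.1)
  expect_equal(u1$W, u2$W, tolerance = 1e-12)
})

test_that("CD-1 training raises the exact log-likelihood of a point mass", {
  r <- rbm(3, 2, seed = 2)
  target <- matrix(c(1, 0, 1), 1)
  batch <- target[rep(1, 20), , drop = FALSE]
  ll0 <- exact_loglik(r, target)
  set.seed(7)
  for (i in 1:200) r <- cd_update(r, batch, k = 1, lr = 0.05)
  expect_gt(exact_loglik(r, target), ll0)
})

test_that("exact-gradient ascent monotonically increases the likelihood", {
  r <- make_small_rbm(3, 2, seed = 11, sd = 0.3)
  data <- matrix(c(1, 0, 1, 1, 1, 0), 2, 3, byrow = TRUE)
  lr <- 0.2
  ll <- exact_loglik(r, data)
  for (step in 1:25) {
    g <- numeric_loglik_grad(r, data)
    r$W <- r$W + lr * g$W
    r$vbias <- r$vbias + lr * g$vbias
    r$hbias <- r$hbias + lr * g$hbias
    ll_new <- exact_loglik(r, data)
    expect_gt(ll_new, ll - 1e-12)
    ll <- ll_new
  }
})

test_that("CD updates are near-stationary on the model's own samples", {
  r <- make_small_rbm(3, 2, seed = 13, sd = 0.4)
  # exact samples from P(v) by enumeration
  states <- semgfusion:::all_binary_states(3)
  pv <- exp(vapply(seq_len(8), function(i) {
    exact_loglik(r, states[i, , drop = FALSE])
  }, 0))
  set.seed(5)
  n <- 4000
  idx <- sample.int(8, n, replace = TRUE, prob = pv)
  r2 <- r
  for (start in seq(1, n, by = 50)) {
    r2 <- cd_update(r2, states[idx[start:(start + 49)], ], k = 1, lr = 0.02)
  }
  drift <- max(abs(r2$W - r$W))
  expect_lt(drift, 0.15)
})

test_that("greedy pretraining builds the configured stack deterministically", {
  set.seed(3)
  x <- matrix(rnorm(60 * 8), 60, 8)
  cfg <- dbn_config(layer_sizes = c(8, 4, 3), n_classes = 3,
                    pretrain_epochs = 6, seed = 5)
  st <- pretrain(cfg, x)
  expect_length(st$rbms, 2)
  expect_equal(dim(st$rbms[[1]]$W), c(8, 4))
  expect_equal(dim(st$rbms[[2]]$W), c(4, 3))
  expect_identical(st$rbms[[1]]$visible, "gaussian")
  expect_identical(st$rbms[[2]]$visible, "bernoulli")
  # reconstruction error of layer 1 improves over pretraining
  expect_lt(st$recon_error[cfg$pretrain_epochs, 1], st$recon_error[1, 1])
  st2 <- pretrain(cfg, x)
  expect_identical(st$rbms[[1]]$W, st2$rbms[[1]]$W)
  expect_error(pretrain(cfg, x[, 1:5]), "does not match")
})

separable_toy <- function(n = 60, seed = 1) {
  set.seed(seed)
  cls <- rep(1:3, each = n / 3)
  x <- matrix(rnorm(n * 10, sd = 0.3), n, 10)
  for (i in seq_len(n)) x[i, cls[i] * 3] <- x[i, cls[i] * 3] + 3
  list(x = x, cls = cls)
}

test_that("fine-tuning learns separable toy classes", {
  toy <- separable_toy()
  cfg <- dbn_config(layer_sizes = c(10, 8, 6), n_classes = 3,
                    pretrain_epochs = 5, finetune_epochs = 100,
                    finetune_lr = 0.01, seed = 4)
  st <- pretrain(cfg, toy$x)
  fit <- finetune(st, toy$x, toy$cls, cfg)
  probs <- predict(fit, toy$x, type = "prob")
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
  expect_gte(accuracy(predict(fit, toy$x), toy$cls), 95)
  expect_lt(utils::tail(fit$history$loss, 1), fit$history$loss[1])
  expect_error(finetune(st, toy$x, toy$cls + 5, cfg), "1..3")
})

test_that("a zero learning rate leaves the pretrained weights untouched", {
  toy <- separable_toy()
  cfg <- dbn_config(layer_sizes = c(10, 8, 6), n_classes = 3,
                    pretrain_epochs = 2, finetune_epochs = 1,
                    finetune_lr = 0, seed = 4)
  st <- pretrain(cfg, toy$x)
  fit <- finetune(st, toy$x, toy$cls, cfg)
  expect_identical(fit$layers[[1]]$W, st$rbms[[1]]$W)
  expect_identical(fit$layers[[2]]$W, st$rbms[[2]]$W)
})

test_that("the fully connected baseline meets the same contract", {
  toy <- separable_toy()
  cfg <- dbn_config(layer_sizes = c(10, 8, 6), n_classes = 3,
                    finetune_epochs = 100, finetune_lr = 0.01, seed = 4)
  fit <- fc_baseline(toy$x, toy$cls, cfg)
  expect_s3_class(fit, "fc_classifier")
  probs <- predict(fit, toy$x, type = "prob")
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-6)
  expect_gte(accuracy(predict(fit, toy$x), toy$cls), 95)
  expect_false(fit$pretrained)
  # same seed twice -> identical fit
  fit2 <- fc_baseline(toy$x, toy$cls, cfg)
  expect_identical(fit$head$W, fit2$head$W)
})

test_that("tidy and glance summarize training", {
  toy <- separable_toy()
  cfg <- dbn_config(layer_sizes = c(10, 6, 4), n_classes = 3,
                    pretrain_epochs = 2, finetune_epochs = 5, seed = 2)
  fit <- finetune(pretrain(cfg, toy$x), toy$x, toy$cls, cfg)
  td <- tidy(fit)
  expect_identical(names(td), c("epoch", "loss", "accuracy"))
  expect_identical(nrow(td), 5L)
  gl <- glance(fit)
  expect_identical(nrow(gl), 1L)
  expect_true(gl$pretrained)
  expect_equal(gl$n_parameters, 10 * 6 + 6 + 6 * 4 + 4 + 4 * 3 + 3)
})
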