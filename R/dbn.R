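# Deep belief network classifier: greedily pretrained stack of restricted
# Boltzmann machines (Gaussian visible units for the real-valued CNN
# features, Bernoulli above) unrolled into a sigmoid MLP with a softmax head
# and fine-tuned end-to-end with Adam on cross-entropy.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Create a restricted Boltzmann machine
#'
#' @param n_visible,n_hidden Unit counts.
#' @param visible `"bernoulli"` or `"gaussian"` (unit-variance Gaussian
#'   visible units for real-valued inputs; standardize inputs first).
#' @param seed Integer seed for the small random weight init.
#' @return An object of class `rbm`: `W` (`[n_visible x n_hidden]`), `vbias`,
#'   `hbias`, `visible`.
#' @export
rbm <- function(n_visible, n_hidden, visible = c("bernoulli", "gaussian"),
                seed = 0) {
  visible <- match.arg(visible)
  stopifnot(n_visible >= 1, n_hidden >= 1)
  w <- with_seed(derive_seed(seed, 33301), function() {
    matrix(stats::rnorm(n_visible * n_hidden, sd = 0.01), n_visible, n_hidden)
  })
  structure(list(W = w, vbias = numeric(n_visible), hbias = numeric(n_hidden),
                 visible = visible, n_visible = as.integer(n_visible),
                 n_hidden = as.integer(n_hidden)),
            class = "rbm")
}

#' @export
print.rbm <- function(x, ...) {
  cat("<rbm>", x$n_visible, "visible (", x$visible, ") x", x$n_hidden,
      "hidden\n")
  invisible(x)
}

as_row_matrix <- function(v, n_cols) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  if (ncol(v) != n_cols) {
    stop("expected ", n_cols, " columns, got ", ncol(v), call. = FALSE)
  }
  v
}

#' Hidden-unit probabilities and samples given visible data
#'
#' `p(h_j = 1 | v) = logistic(v' W_j + c_j)`; hidden units are conditionally
#' independent given v.
#'
#' @param object An [rbm()].
#' @param v Visible vector or `[n x n_visible]` matrix.
#' @param seed Optional seed for the Bernoulli sampling.
#' @return List with `prob` and `sample`, both `[n x n_hidden]`.
#' @export
sample_h_given_v <- function(object, v, seed = NULL) {
  stopifnot(inherits(object, "rbm"))
  v <- as_row_matrix(v, object$n_visible)
  p <- sigmoid(v %*% object$W + rep(object$hbias, each = nrow(v)))
  draw <- function() matrix(stats::runif(length(p)) < p, nrow(p), ncol(p)) * 1
  s <- if (is.null(seed)) draw() else with_seed(seed, draw)
  list(prob = p, sample = s)
}

#' Visible-unit reconstruction given hidden states
#'
#' Bernoulli visibles give `logistic(h W' + b)` probabilities; Gaussian
#' visibles give the conditional mean `h W' + b`.
#'
#' @inheritParams sample_h_given_v
#' @param h Hidden vector or `[n x n_hidden]` matrix.
#' @return List with `prob` (probabilities or means) and `sample`.
#' @export
sample_v_given_h <- function(object, h, seed = NULL) {
  stopifnot(inherits(object, "rbm"))
  h <- as_row_matrix(h, object$n_hidden)
  a <- tcrossprod(h, object$W) + rep(object$vbias, each = nrow(h))
  if (object$visible == "bernoulli") {
    p <- sigmoid(a)
    draw <- function() matrix(stats::runif(length(p)) < p, nrow(p), ncol(p)) * 1
    s <- if (is.null(seed)) draw() else with_seed(seed, draw)
    list(prob = p, sample = s)
  } else {
    draw <- function() a + matrix(stats::rnorm(length(a)), nrow(a), ncol(a))
    s <- if (is.null(seed)) draw() else with_seed(seed, draw)
    list(prob = a, sample = s)
  }
}

#' One contrastive-divergence (CD-k) parameter update
#'
#' Estimates the log-likelihood gradient with k mean-field Gibbs steps
#' started at the data: hidden and visible states are propagated as
#' probabilities/means rather than binary samples, so the update is
#' deterministic given the batch (duplicating a case leaves the averaged
#' update unchanged). Parameters move by `lr` times the batch-averaged
#' estimate.
#'
#' @param object An [rbm()].
#' @param batch `[n x n_visible]` data matrix (rows are cases).
#' @param k Number of Gibbs steps.
#' @param lr Learning rate; `lr = 0` leaves parameters unchanged.
#' @return The updated `rbm`.
#' @export
cd_update <- function(object, batch, k = 1, lr = 0.01) {
  stopifnot(inherits(object, "rbm"), k >= 1)
  batch <- as_row_matrix(batch, object$n_visible)
  n <- nrow(batch)
  ph0 <- sample_h_given_v(object, batch)
  h <- ph0$prob
  v <- batch
  for (step in seq_len(k)) {
    v <- sample_v_given_h(object, h)$prob
    h <- sample_h_given_v(object, v)$prob
  }
  pos <- crossprod(batch, ph0$prob) / n
  neg <- crossprod(v, h) / n
  object$W <- object$W + lr * (pos - neg)
  object$vbias <- object$vbias + lr * colMeans(batch - v)
  object$hbias <- object$hbias + lr * colMeans(ph0$prob - h)
  object
}

rbm_free_energy <- function(object, v) {
  v <- as_row_matrix(v, object$n_visible)
  a <- v %*% object$W + rep(object$hbias, each = nrow(v))
  vis <- if (object$visible == "bernoulli") {
    -as.vector(v %*% object$vbias)
  } else {
    rowSums(0.5 * sweep(v, 2, object$vbias)^2)
  }
  vis - rowSums(log1p(exp(a)))
}

all_binary_states <- function(n) {
  as.matrix(expand.grid(rep(list(c(0, 1)), n)))[, n:1, drop = FALSE] * 1
}

#' Exact average log-likelihood of a small Bernoulli RBM
#'
#' Computes `mean(log P(v))` with the partition function obtained by
#' exhaustive enumeration of all visible states (hidden units are summed out
#' analytically through the free energy). Only enumerable machines are
#' accepted: `n_visible + n_hidden <= 20`.
#'
#' @param object A Bernoulli-visible [rbm()].
#' @param data `[n x n_visible]` binary matrix.
#' @return Average log-likelihood (scalar).
#' @export
exact_loglik <- function(object, data) {
  stopifnot(inherits(object, "rbm"))
  if (object$visible != "bernoulli") {
    stop("exact enumeration implemented for Bernoulli visible units only",
         call. = FALSE)
  }
  if (object$n_visible + object$n_hidden > 20) {
    stop("RBM too large to enumerate (n_visible + n_hidden > 20)", call. = FALSE)
  }
  states <- all_binary_states(object$n_visible)
  log_z <- log(sum(exp(-rbm_free_energy(object, states))))
  mean(-rbm_free_energy(object, data) - log_z)
}

#' DBN classifier configuration
#'
#' The full-scale stack is 50,176 -> 1024 -> 1500 with a 12-way softmax head;
#' pretraining hyperparameters default to CD-1, learning rate 1e-3, 10
#' epochs.
#'
#' @param layer_sizes Integer vector: input dimension then hidden sizes.
#' @param n_classes Number of classes for the softmax head.
#' @param cd_steps CD-k steps during pretraining.
#' @param pretrain_epochs,pretrain_lr,pretrain_batch Pretraining schedule.
#' @param finetune_epochs,finetune_lr,finetune_batch Fine-tuning schedule.
#' @param train_extractor Backpropagate into the convolutional extractor
#'   during fine-tuning (joint mode)?
#' @param seed Integer seed governing all training randomness.
#' @return An object of class `dbn_config`.
#' @export
dbn_config <- function(layer_sizes = c(50176, 1024, 1500), n_classes = 12,
                       cd_steps = 1, pretrain_epochs = 10, pretrain_lr = 1e-3,
                       pretrain_batch = 32, finetune_epochs = 30,
                       finetune_lr = 1e-3, finetune_batch = 32,
                       train_extractor = FALSE, seed = 0) {
  stopifnot(length(layer_sizes) >= 2, all(layer_sizes >= 1), n_classes >= 2)
  structure(
    list(layer_sizes = as.integer(layer_sizes), n_classes = as.integer(n_classes),
         cd_steps = as.integer(cd_steps),
         pretrain_epochs = as.integer(pretrain_epochs),
         pretrain_lr = pretrain_lr, pretrain_batch = as.integer(pretrain_batch),
         finetune_epochs = as.integer(finetune_epochs),
         finetune_lr = finetune_lr, finetune_batch = as.integer(finetune_batch),
         train_extractor = isTRUE(train_extractor), seed = as.integer(seed)),
    class = "dbn_config"
  )
}

#' Greedy layer-wise pretraining of the RBM stack
#'
#' Features are standardized per dimension (the first RBM has Gaussian
#' visible units); each subsequent RBM is Bernoulli and trains on the hidden
#' probabilities of the layer below. Deterministic under the config seed.
#'
#' @param config A [dbn_config()]; `layer_sizes[1]` must equal
#'   `ncol(features)`.
#' @param features `[n x d]` real-valued feature matrix.
#' @return An object of class `rbm_stack`: list of [rbm()]s plus the
#'   standardization constants and per-epoch reconstruction errors.
#' @export
pretrain <- function(config, features) {
  stopifnot(inherits(config, "dbn_config"))
  features <- as.matrix(features)
  if (ncol(features) != config$layer_sizes[1]) {
    stop("feature dimension ", ncol(features), " does not match first layer ",
         config$layer_sizes[1], call. = FALSE)
  }
  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[scale < 1e-8] <- 1
  x <- sweep(sweep(features, 2, center), 2, scale, "/")
  sizes <- config$layer_sizes
  rbms <- vector("list", length(sizes) - 1)
  recon <- matrix(NA_real_, config$pretrain_epochs, length(rbms))
  with_seed(derive_seed(config$seed, 881), function() {
    inp <- x
    for (l in seq_along(rbms)) {
      r <- rbm(sizes[l], sizes[l + 1],
               visible = if (l == 1) "gaussian" else "bernoulli",
               seed = derive_seed(config$seed, 882, l))
      n <- nrow(inp)
      for (ep in seq_len(config$pretrain_epochs)) {
        ord <- sample.int(n)
        for (start in seq(1, n, by = config$pretrain_batch)) {
          idx <- ord[start:min(start + config$pretrain_batch - 1, n)]
          r <- cd_update(r, inp[idx, , drop = FALSE], k = config$cd_steps,
                         lr = config$pretrain_lr)
        }
        ph <- sample_h_given_v(r, inp)$prob
        vr <- sample_v_given_h(r, ph)$prob
        recon[ep, l] <<- mean((inp - vr)^2)
      }
      rbms[[l]] <<- r
      inp <- sample_h_given_v(r, inp)$prob
    }
  })
  structure(list(rbms = rbms, center = center, scale = scale,
                 recon_error = recon, config = config),
            class = "rbm_stack")
}

#' @export
print.rbm_stack <- function(x, ...) {
  cat("<rbm_stack>", paste(x$config$layer_sizes, collapse = " -> "), "\n")
  invisible(x)
}

mlp_forward <- function(layers, head, x) {
  acts <- list()
  a <- x
  for (l in seq_along(layers)) {
    a <- sigmoid(a %*% layers[[l]]$W + rep(layers[[l]]$b, each = nrow(a)))
    acts[[l]] <- a
  }
  logits <- a %*% head$W + rep(head$b, each = nrow(a))
  logits <- logits - apply(logits, 1, max)
  p <- exp(logits)
  p <- p / rowSums(p)
  list(acts = acts, prob = p)
}

mlp_backward <- function(layers, head, x, acts, prob, y_onehot) {
  n <- nrow(x)
  dlogit <- (prob - y_onehot) / n
  a_last <- if (length(acts)) acts[[length(acts)]] else x
  grads <- list(head = list(W = crossprod(a_last, dlogit), b = colSums(dlogit)),
                layers = vector("list", length(layers)))
  da <- tcrossprod(dlogit, head$W)
  for (l in rev(seq_along(layers))) {
    a <- acts[[l]]
    dz <- da * a * (1 - a)
    inp <- if (l > 1) acts[[l - 1]] else x
    grads$layers[[l]] <- list(W = crossprod(inp, dz), b = colSums(dz))
    da <- tcrossprod(dz, layers[[l]]$W)
  }
  grads$dx <- da
  grads
}

new_classifier <- function(layers, head, center, scale, config, history,
                           pretrained, extractor = NULL) {
  structure(list(layers = layers, head = head, center = center, scale = scale,
                 config = config, history = history, pretrained = pretrained,
                 extractor = extractor),
            class = c(if (pretrained) "dbn_classifier" else "fc_classifier",
                      "semg_classifier"))
}

train_head <- function(layers, head, features, labels, config, center, scale,
                       extractor = NULL, images = NULL, pretrained = TRUE) {
  n_classes <- config$n_classes
  if (any(labels < 1 | labels > n_classes)) {
    stop("labels must lie in 1..", n_classes, call. = FALSE)
  }
  y <- diag(n_classes)[labels, , drop = FALSE]
  joint <- !is.null(extractor)
  x_std <- sweep(sweep(as.matrix(features), 2, center), 2, scale, "/")
  n <- nrow(x_std)
  model <- list(layers = layers, head = head)
  ext_state <- adam_state()
  mlp_state <- adam_state()
  history <- vector("list", config$finetune_epochs)
  with_seed(derive_seed(config$seed, 919), function() {
    for (ep in seq_len(config$finetune_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      ep_correct <- 0
      for (start in seq(1, n, by = config$finetune_batch)) {
        idx <- ord[start:min(start + config$finetune_batch - 1, n)]
        if (joint) {
          fw <- mffn_forward(extractor, images[, , , idx, drop = FALSE],
                             train = TRUE)
          extractor <<- fw$model
          flat <- matrix(fw$y, nrow = prod(dim(fw$y)[1:3]), ncol = length(idx))
          xb <- sweep(sweep(t(flat), 2, center), 2, scale, "/")
        } else {
          xb <- x_std[idx, , drop = FALSE]
        }
        fwd <- mlp_forward(model$layers, model$head, xb)
        p_true <- fwd$prob[cbind(seq_along(idx), labels[idx])]
        ep_loss <- ep_loss + sum(-log(pmax(p_true, 1e-12)))
        ep_correct <- ep_correct +
          sum(max.col(fwd$prob) == labels[idx])
        g <- mlp_backward(model$layers, model$head, xb, fwd$acts, fwd$prob,
                          y[idx, , drop = FALSE])
        upd <- adam_apply(model, list(layers = g$layers, head = g$head),
                          mlp_state, lr = config$finetune_lr)
        model <<- upd$model
        mlp_state <<- upd$state
        if (joint) {
          dflat <- sweep(g$dx, 2, scale, "/")
          dy <- array(t(dflat), dim = dim(fw$y))
          bwd <- mffn_backward(extractor, fw$caches, dy)
          uext <- adam_apply(extractor, bwd$grads, ext_state,
                             lr = config$finetune_lr)
          extractor <<- uext$model
          ext_state <<- uext$state
        }
      }
      history[[ep]] <<- tibble::tibble(epoch = ep, loss = ep_loss / n,
                                       accuracy = 100 * ep_correct / n)
    }
  })
  new_classifier(model$layers, model$head, center, scale, config,
                 dplyr::bind_rows(history), pretrained,
                 extractor = if (joint) extractor else NULL)
}

#' Supervised fine-tuning of a pretrained stack with a softmax head
#'
#' Unrolls the RBM stack into a sigmoid MLP (weights and hidden biases become
#' the layer parameters), attaches a randomly initialized `n_classes`-way
#' softmax head, and trains all layers with Adam on cross-entropy. With
#' `config$train_extractor = TRUE` (and `extractor`/`images` supplied) the
#' gradient also flows into the convolutional extractor (joint mode).
#'
#' @param stack An [pretrain()]ed `rbm_stack`.
#' @param features `[n x d]` feature matrix (raw scale; the stack's
#'   standardization constants are applied).
#' @param labels Integer class labels in `1..n_classes`.
#' @param config A [dbn_config()].
#' @param extractor,images Optional `mffn` and `[H, W, 3, N]` image batch for
#'   joint fine-tuning.
#' @return An object of class `dbn_classifier`.
#' @export
finetune <- function(stack, features, labels, config = stack$config,
                     extractor = NULL, images = NULL) {
  stopifnot(inherits(stack, "rbm_stack"))
  layers <- lapply(stack$rbms, function(r) list(W = r$W, b = r$hbias))
  d_last <- config$layer_sizes[length(config$layer_sizes)]
  head <- with_seed(derive_seed(config$seed, 920), function() {
    list(W = matrix(stats::rnorm(d_last * config$n_classes,
                                 sd = sqrt(1 / d_last)),
                    d_last, config$n_classes),
         b = numeric(config$n_classes))
  })
  use_joint <- config$train_extractor && !is.null(extractor)
  train_head(layers, head, features, labels, config,
             stack$center, stack$scale,
             extractor = if (use_joint) extractor else NULL,
             images = if (use_joint) images else NULL,
             pretrained = TRUE)
}

#' Fully connected baseline classifier
#'
#' Same layer sizes, activation, head and training schedule as [finetune()]
#' but with randomly initialized dense layers and no generative pretraining —
#' the classical comparison against the DBN head.
#'
#' @inheritParams finetune
#' @param features `[n x d]` feature matrix.
#' @return An object of class `fc_classifier`.
#' @export
fc_baseline <- function(features, labels, config) {
  stopifnot(inherits(config, "dbn_config"))
  features <- as.matrix(features)
  if (ncol(features) != config$layer_sizes[1]) {
    stop("feature dimension does not match first layer size", call. = FALSE)
  }
  center <- colMeans(features)
  scale <- apply(features, 2, stats::sd)
  scale[scale < 1e-8] <- 1
  sizes <- config$layer_sizes
  layers <- with_seed(derive_seed(config$seed, 921), function() {
    lapply(seq_len(length(sizes) - 1), function(l) {
      list(W = matrix(stats::rnorm(sizes[l] * sizes[l + 1],
                                   sd = sqrt(1 / sizes[l])),
                      sizes[l], sizes[l + 1]),
           b = numeric(sizes[l + 1]))
    })
  })
  d_last <- sizes[length(sizes)]
  head <- with_seed(derive_seed(config$seed, 922), function() {
    list(W = matrix(stats::rnorm(d_last * config$n_classes,
                                 sd = sqrt(1 / d_last)),
                    d_last, config$n_classes),
         b = numeric(config$n_classes))
  })
  train_head(layers, head, features, labels, config, center, scale,
             pretrained = FALSE)
}

#' Predict classes or posteriors from a fitted classifier
#'
#' @param object A `dbn_classifier` or `fc_classifier`.
#' @param features `[n x d]` feature matrix on the raw scale.
#' @param type `"class"` for hard labels, `"prob"` for the softmax
#'   posteriors.
#' @param ... Unused.
#' @return Integer labels or a `[n x n_classes]` probability matrix.
#' @export
predict.semg_classifier <- function(object, features,
                                    type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- sweep(sweep(as.matrix(features), 2, object$center), 2, object$scale, "/")
  p <- mlp_forward(object$layers, object$head, x)$prob
  if (type == "prob") p else max.col(p)
}

#' @export
print.semg_classifier <- function(x, ...) {
  cat("<", class(x)[1], "> ",
      paste(c(x$config$layer_sizes, x$config$n_classes), collapse = " -> "),
      if (x$pretrained) " (CD-pretrained)" else " (random init)",
      sprintf("; final train accuracy %.1f%%\n",
              utils::tail(x$history$accuracy, 1)), sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-epoch training history of a fitted classifier
#'
#' @param x A `dbn_classifier` or `fc_classifier`.
#' @param ... Unused.
#' @return Tibble with columns `epoch`, `loss`, `accuracy`.
#' @method tidy semg_classifier
#' @export
tidy.semg_classifier <- function(x, ...) x$history

#' One-row training summary of a fitted classifier
#'
#' @param x A `dbn_classifier` or `fc_classifier`.
#' @param ... Unused.
#' @return One-row tibble: final loss/accuracy, epoch count, parameter
#'   count, pretraining flag.
#' @method glance semg_classifier
#' @export
glance.semg_classifier <- function(x, ...) {
  n_par <- sum(vapply(x$layers, function(l) length(l$W) + length(l$b), 0)) +
    length(x$head$W) + length(x$head$b)
  tibble::tibble(
    final_loss = utils::tail(x$history$loss, 1),
    final_train_accuracy = utils::tail(x$history$accuracy, 1),
    epochs = nrow(x$history),
    n_parameters = n_par,
    pretrained = x$pretrained
  )
}
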