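# Multiple feature fusion network: stem convolution + pooling, two dense
# blocks with pre-activation composite layers (BN-ReLU-1x1 conv-BN-ReLU-3x3
# conv), transition layers (BN-ReLU-1x1 conv-2x2 average pool) between and
# after them. Features are taken at the second transition layer's output.

#' MFFN feature-extractor configuration
#'
#' Defaults realize the full-scale plan: 224x224x3 input, a 7x7/stride-2
#' 64-filter stem, 3x3/stride-2 max pooling, dense blocks of 6 and 12
#' composite layers with growth rate 32 and 4x bottleneck, and 0.5
#' channel compression in the transition layers. That arithmetic yields
#' 64 + 6*32 = 256 channels after block 1, 128 + 12*32 = 512 after block 2,
#' and a 14 x 14 x 256 extraction point (50,176 values flattened).
#'
#' @param input_size Input image height = width in pixels.
#' @param input_planes Input planes (3 for RGB).
#' @param stem_filters,stem_kernel,stem_stride,stem_pad Stem convolution.
#' @param pool_size,pool_stride,pool_pad Stem max pooling.
#' @param block_sizes Integer vector of dense-layer counts per block.
#' @param growth Growth rate k: channels added by each dense layer.
#' @param bottleneck_factor Width of the 1x1 bottleneck conv, in units of k.
#' @param compression Transition-layer channel factor theta in (0, 1].
#' @return An object of class `mffn_config`.
#' @export
mffn_config <- function(input_size = 224, input_planes = 3,
                        stem_filters = 64, stem_kernel = 7, stem_stride = 2,
                        stem_pad = 3, pool_size = 3, pool_stride = 2,
                        pool_pad = 1, block_sizes = c(6, 12), growth = 32,
                        bottleneck_factor = 4, compression = 0.5) {
  stopifnot(growth > 0, compression > 0, compression <= 1,
            all(block_sizes >= 0), length(block_sizes) >= 1,
            input_size >= 1, input_planes >= 1)
  structure(
    list(input_size = as.integer(input_size),
         input_planes = as.integer(input_planes),
         stem_filters = as.integer(stem_filters),
         stem_kernel = as.integer(stem_kernel),
         stem_stride = as.integer(stem_stride),
         stem_pad = as.integer(stem_pad),
         pool_size = as.integer(pool_size),
         pool_stride = as.integer(pool_stride),
         pool_pad = as.integer(pool_pad),
         block_sizes = as.integer(block_sizes),
         growth = as.integer(growth),
         bottleneck_factor = as.integer(bottleneck_factor),
         compression = compression),
    class = "mffn_config"
  )
}

conv_out_size <- function(h, k, s, p, what) {
  v <- h + 2 * p - k
  if (v < 0) stop("spatial size too small for ", what, call. = FALSE)
  v %/% s + 1
}

#' Symbolic stage-by-stage shape plan
#'
#' Propagates shapes through the architecture without allocating any model,
#' and raises the same shape errors a real forward pass would (e.g. odd
#' spatial dimensions reaching a transition layer's 2x2 average pooling).
#'
#' @param config An [mffn_config()].
#' @return A tibble of class `shape_plan` with columns `stage`, `height`,
#'   `width`, `channels`.
#' @examples
#' shape_plan(mffn_config())
#' @export
shape_plan <- function(config = mffn_config()) {
  stopifnot(inherits(config, "mffn_config"))
  h <- config$input_size
  c <- config$input_planes
  rows <- list(list(stage = "input", height = h, width = h, channels = c))
  h <- conv_out_size(h, config$stem_kernel, config$stem_stride,
                     config$stem_pad, "stem convolution")
  c <- config$stem_filters
  rows <- c(rows, list(list(stage = "convolution", height = h, width = h,
                            channels = c)))
  h <- conv_out_size(h, config$pool_size, config$pool_stride,
                     config$pool_pad, "stem pooling")
  rows <- c(rows, list(list(stage = "pooling", height = h, width = h,
                            channels = c)))
  for (b in seq_along(config$block_sizes)) {
    c <- c + config$block_sizes[b] * config$growth
    rows <- c(rows, list(list(stage = sprintf("dense_block_%d", b),
                              height = h, width = h, channels = c)))
    c <- floor(config$compression * c)
    if (h %% 2 != 0) {
      stop("transition layer ", b, " requires even spatial size, got ", h,
           call. = FALSE)
    }
    h <- h %/% 2
    rows <- c(rows, list(list(stage = sprintf("transition_%d", b),
                              height = h, width = h, channels = c)))
  }
  rows <- c(rows, list(list(stage = "flatten", height = 1, width = 1,
                            channels = h * h * c)))
  out <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  class(out) <- c("shape_plan", class(out))
  out
}

make_dense_layer <- function(c_in, growth, bottleneck_factor) {
  width <- bottleneck_factor * growth
  list(bn1 = layer_bn(c_in),
       conv1 = layer_conv(1, 1, c_in, width),
       bn2 = layer_bn(width),
       conv2 = layer_conv(3, 3, width, growth, pad = 1))
}

make_dense_block <- function(c_in, n_layers, growth, bottleneck_factor) {
  layers <- vector("list", n_layers)
  input_indices <- vector("list", n_layers)
  c_cur <- c_in
  for (j in seq_len(n_layers)) {
    layers[[j]] <- make_dense_layer(c_cur, growth, bottleneck_factor)
    input_indices[[j]] <- 0:(j - 1) # consumes block input + all prior outputs
    c_cur <- c_cur + growth
  }
  list(layers = layers, c_in = c_in, growth = growth,
       input_indices = input_indices)
}

make_transition <- function(c_in, compression) {
  c_out <- floor(compression * c_in)
  list(bn = layer_bn(c_in), conv = layer_conv(1, 1, c_in, c_out),
       c_in = c_in, c_out = c_out)
}

#' Build the MFFN feature extractor
#'
#' Allocates all layers (Kaiming fan-in convolution init, unit-scale
#' batch-norm) for the given configuration; initialization is deterministic
#' for a fixed seed. The realized forward-pass shapes equal [shape_plan()].
#'
#' @param config An [mffn_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `mffn` (the feature extractor).
#' @export
build_mffn <- function(config = mffn_config(), seed = 0) {
  plan <- shape_plan(config) # validates the stride chain up front
  with_seed(derive_seed(seed, 40127), function() {
    c_cur <- config$stem_filters
    blocks <- list()
    transitions <- list()
    for (b in seq_along(config$block_sizes)) {
      blocks[[b]] <- make_dense_block(c_cur, config$block_sizes[b],
                                      config$growth, config$bottleneck_factor)
      c_cur <- c_cur + config$block_sizes[b] * config$growth
      transitions[[b]] <- make_transition(c_cur, config$compression)
      c_cur <- transitions[[b]]$c_out
    }
    structure(
      list(config = config,
           stem = list(conv = layer_conv(config$stem_kernel, config$stem_kernel,
                                         config$input_planes,
                                         config$stem_filters,
                                         stride = config$stem_stride,
                                         pad = config$stem_pad),
                       bn = layer_bn(config$stem_filters),
                       pool = layer_maxpool(config$pool_size,
                                            config$pool_stride,
                                            config$pool_pad)),
           blocks = blocks, transitions = transitions, plan = plan),
      class = "mffn"
    )
  })
}

#' @export
print.mffn <- function(x, ...) {
  cat("<mffn> blocks (", paste(x$config$block_sizes, collapse = ", "),
      "), growth ", x$config$growth, ", extraction shape ",
      paste(utils::tail(x$plan, 2)$height[1], utils::tail(x$plan, 2)$width[1],
            utils::tail(x$plan, 2)$channels[1], sep = " x "), "\n", sep = "")
  invisible(x)
}

cat_channels <- function(a, b) {
  da <- dim(a)
  db <- dim(b)
  out <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  out[, , seq_len(da[3]), ] <- a
  out[, , da[3] + seq_len(db[3]), ] <- b
  out
}

dense_layer_fwd <- function(layer, x, train) {
  f1 <- nn_forward(layer$bn1, x, train)
  r1 <- nn_forward(layer_relu(), f1$y)
  c1 <- nn_forward(layer$conv1, r1$y)
  f2 <- nn_forward(layer$bn2, c1$y, train)
  r2 <- nn_forward(layer_relu(), f2$y)
  c2 <- nn_forward(layer$conv2, r2$y)
  layer$bn1 <- f1$layer
  layer$bn2 <- f2$layer
  list(y = c2$y, layer = layer,
       cache = list(bn1 = f1$cache, r1 = r1$cache, conv1 = c1$cache,
                    bn2 = f2$cache, r2 = r2$cache, conv2 = c2$cache))
}

dense_layer_bwd <- function(layer, cache, dy) {
  b <- nn_backward(layer$conv2, cache$conv2, dy)
  g <- list(conv2 = b$grads)
  b2 <- nn_backward(layer_relu(), cache$r2, b$dx)
  b3 <- nn_backward(layer$bn2, cache$bn2, b2$dx)
  g$bn2 <- b3$grads
  b4 <- nn_backward(layer$conv1, cache$conv1, b3$dx)
  g$conv1 <- b4$grads
  b5 <- nn_backward(layer_relu(), cache$r1, b4$dx)
  b6 <- nn_backward(layer$bn1, cache$bn1, b5$dx)
  g$bn1 <- b6$grads
  list(dx = b6$dx, grads = g)
}

dense_block_fwd <- function(block, x, train) {
  concat <- x
  caches <- vector("list", length(block$layers))
  for (j in seq_along(block$layers)) {
    res <- dense_layer_fwd(block$layers[[j]], concat, train)
    block$layers[[j]] <- res$layer
    caches[[j]] <- res$cache
    concat <- cat_channels(concat, res$y)
  }
  list(y = concat, block = block, caches = caches)
}

dense_block_bwd <- function(block, caches, dconcat) {
  k <- block$growth
  grads <- vector("list", length(block$layers))
  for (j in rev(seq_along(block$layers))) {
    c_in_j <- block$c_in + (j - 1) * k
    dyj <- dconcat[, , c_in_j + seq_len(k), , drop = FALSE]
    res <- dense_layer_bwd(block$layers[[j]], caches[[j]], dyj)
    grads[[j]] <- res$grads
    dconcat <- dconcat[, , seq_len(c_in_j), , drop = FALSE] + res$dx
  }
  list(dx = dconcat, grads = list(layers = grads))
}

transition_fwd <- function(tr, x, train) {
  f <- nn_forward(tr$bn, x, train)
  r <- nn_forward(layer_relu(), f$y)
  c <- nn_forward(tr$conv, r$y)
  p <- nn_forward(layer_avgpool2(), c$y)
  tr$bn <- f$layer
  list(y = p$y, tr = tr,
       cache = list(bn = f$cache, r = r$cache, conv = c$cache, pool = p$cache))
}

transition_bwd <- function(tr, cache, dy) {
  b <- nn_backward(layer_avgpool2(), cache$pool, dy)
  b2 <- nn_backward(tr$conv, cache$conv, b$dx)
  b3 <- nn_backward(layer_relu(), cache$r, b2$dx)
  b4 <- nn_backward(tr$bn, cache$bn, b3$dx)
  list(dx = b4$dx, grads = list(bn = b4$grads, conv = b2$grads))
}

#' Forward pass through the MFFN
#'
#' Lower-level API used by [extract_features()] and by joint fine-tuning.
#'
#' @param model An [build_mffn()] extractor.
#' @param x Input array `[H, W, planes, N]`.
#' @param train Use batch statistics (and cache for backprop)?
#' @return List with `y` (extraction-point features `[h, w, c, N]`), the
#'   updated `model` (batch-norm running statistics), and `caches` for
#'   [mffn_backward()].
#' @export
mffn_forward <- function(model, x, train = FALSE) {
  stopifnot(inherits(model, "mffn"), length(dim(x)) == 4)
  if (dim(x)[1] != model$config$input_size ||
      dim(x)[2] != model$config$input_size ||
      dim(x)[3] != model$config$input_planes) {
    stop("input shape ", paste(dim(x)[1:3], collapse = "x"),
         " does not match configured input ", model$config$input_size, "x",
         model$config$input_size, "x", model$config$input_planes,
         call. = FALSE)
  }
  caches <- list()
  s <- nn_forward(model$stem$conv, x)
  caches$stem_conv <- s$cache
  b <- nn_forward(model$stem$bn, s$y, train)
  model$stem$bn <- b$layer
  caches$stem_bn <- b$cache
  r <- nn_forward(layer_relu(), b$y)
  caches$stem_relu <- r$cache
  p <- nn_forward(model$stem$pool, r$y)
  caches$stem_pool <- p$cache
  y <- p$y
  caches$blocks <- list()
  caches$transitions <- list()
  for (i in seq_along(model$blocks)) {
    db <- dense_block_fwd(model$blocks[[i]], y, train)
    model$blocks[[i]] <- db$block
    caches$blocks[[i]] <- db$caches
    tr <- transition_fwd(model$transitions[[i]], db$y, train)
    model$transitions[[i]] <- tr$tr
    caches$transitions[[i]] <- tr$cache
    y <- tr$y
  }
  list(y = y, model = model, caches = caches)
}

#' Backward pass through the MFFN
#'
#' @param model An `mffn` extractor.
#' @param caches Caches from [mffn_forward()] with `train = TRUE`.
#' @param dy Gradient at the extraction point, same shape as the forward
#'   output.
#' @return List with `dx` (gradient w.r.t. the input image batch) and
#'   `grads` (a tree mirroring the model's trainable parameters).
#' @export
mffn_backward <- function(model, caches, dy) {
  grads <- list(blocks = vector("list", length(model$blocks)),
                transitions = vector("list", length(model$transitions)))
  for (i in rev(seq_along(model$blocks))) {
    tb <- transition_bwd(model$transitions[[i]], caches$transitions[[i]], dy)
    grads$transitions[[i]] <- tb$grads
    bb <- dense_block_bwd(model$blocks[[i]], caches$blocks[[i]], tb$dx)
    grads$blocks[[i]] <- bb$grads
    dy <- bb$dx
  }
  pp <- nn_backward(model$stem$pool, caches$stem_pool, dy)
  rr <- nn_backward(layer_relu(), caches$stem_relu, pp$dx)
  bb <- nn_backward(model$stem$bn, caches$stem_bn, rr$dx)
  cc <- nn_backward(model$stem$conv, caches$stem_conv, bb$dx)
  grads$stem <- list(conv = cc$grads, bn = bb$grads)
  list(dx = cc$dx, grads = grads)
}

#' Run one dense block on a feature array
#'
#' Convenience wrapper over a freshly initialized (seeded) dense block: layer
#' j consumes the concatenation of the block input and all previous layers'
#' outputs, and adds `growth` channels. `n_layers = 0` is the identity.
#'
#' @param x Feature array `[H, W, C, N]` (or `[H, W, C]`, treated as N = 1).
#' @param n_layers Number of composite layers L.
#' @param growth Growth rate k.
#' @param bottleneck_factor Bottleneck width in units of k.
#' @param seed Weight-init seed.
#' @return Feature array with `C + n_layers * growth` channels.
#' @export
dense_block_forward <- function(x, n_layers, growth = 32,
                                bottleneck_factor = 4, seed = 0) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  if (n_layers == 0) return(x)
  block <- with_seed(derive_seed(seed, 577), function() {
    make_dense_block(dim(x)[3], n_layers, growth, bottleneck_factor)
  })
  dense_block_fwd(block, x, train = FALSE)$y
}

#' Run one transition layer on a feature array
#'
#' BN-ReLU-1x1 conv-2x2 average pool: channels become
#' `floor(compression * C)` and spatial dimensions halve. Odd spatial
#' dimensions are a shape error.
#'
#' @inheritParams dense_block_forward
#' @param compression Channel factor theta.
#' @return Feature array `[H/2, W/2, floor(compression * C), N]`.
#' @export
transition_forward <- function(x, compression = 0.5, seed = 0) {
  if (length(dim(x)) == 3) dim(x) <- c(dim(x), 1)
  tr <- with_seed(derive_seed(seed, 578), function() {
    make_transition(dim(x)[3], compression)
  })
  transition_fwd(tr, x, train = FALSE)$y
}

#' Count direct connections realized by a dense block
#'
#' Inspects the recorded input wiring: layer j consumes j earlier feature
#' maps (the block input plus layers 1..j-1), so an L-layer block realizes
#' L(L+1)/2 direct connections.
#'
#' @param model_or_l An `mffn` model (counts block 1) or an integer L (counts
#'   a freshly wired block of that depth).
#' @param block Which block of an `mffn` to inspect.
#' @return Integer connection count.
#' @export
count_dense_connections <- function(model_or_l, block = 1) {
  b <- if (inherits(model_or_l, "mffn")) {
    model_or_l$blocks[[block]]
  } else {
    make_dense_block(1, as.integer(model_or_l), 1, 1)
  }
  sum(lengths(b$input_indices))
}

as_image_batch <- function(images, size, planes) {
  to_arr <- function(im) {
    if (inherits(im, "rgb_image")) im$pixels else im
  }
  if (inherits(images, "rgb_image") ||
      (is.array(images) && length(dim(images)) == 3)) {
    images <- list(to_arr(images))
  } else if (is.array(images) && length(dim(images)) == 4) {
    return(images)
  } else {
    images <- lapply(images, to_arr)
  }
  x <- array(0, c(size, size, planes, length(images)))
  for (i in seq_along(images)) {
    if (!all(dim(images[[i]]) == c(size, size, planes))) {
      stop("image ", i, " has shape ", paste(dim(images[[i]]), collapse = "x"),
           ", expected ", size, "x", size, "x", planes, call. = FALSE)
    }
    x[, , , i] <- images[[i]]
  }
  x
}

#' Extract features at the second transition layer
#'
#' Runs images through the extractor in evaluation mode and returns the
#' extraction-point feature maps plus their flattened vectors (length
#' H * W * C; 50,176 for the full-scale plan). Order is preserved for
#' batches.
#'
#' @param model An `mffn`.
#' @param images An `rgb_image`, a list of them, a `[H, W, 3]` array, or a
#'   `[H, W, 3, N]` batch array.
#' @param batch_size Internal forward batch size.
#' @return For a single image, a `feature_map` (list with `map` and `flat`);
#'   for a batch, a list of `feature_map`s.
#' @export
extract_features <- function(model, images, batch_size = 16) {
  stopifnot(inherits(model, "mffn"))
  single <- inherits(images, "rgb_image") ||
    (is.array(images) && length(dim(images)) == 3)
  x <- as_image_batch(images, model$config$input_size, model$config$input_planes)
  n <- dim(x)[4]
  out <- vector("list", n)
  for (start in seq(1, n, by = batch_size)) {
    idx <- start:min(start + batch_size - 1, n)
    y <- mffn_forward(model, x[, , , idx, drop = FALSE], train = FALSE)$y
    for (j in seq_along(idx)) {
      fm <- y[, , , j, drop = FALSE]
      dim(fm) <- dim(y)[1:3]
      out[[idx[j]]] <- structure(list(map = fm, flat = as.vector(fm)),
                                 class = "feature_map")
    }
  }
  if (single) out[[1]] else out
}

#' Spatial mean of each feature-map channel
#'
#' @param fm A `feature_map` from [extract_features()] or a `[H, W, C]`
#'   array.
#' @return Numeric vector of length C (entry c = mean over H x W of channel
#'   c).
#' @export
channel_mean_profile <- function(fm) {
  m <- if (inherits(fm, "feature_map")) fm$map else fm
  stopifnot(length(dim(m)) == 3)
  apply(m, 3, mean)
}
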