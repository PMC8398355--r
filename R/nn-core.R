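# Minimal CNN engine: conv / batch-norm / ReLU / pooling layers with
# forward and backward passes on [H, W, C, N] arrays. Convolution is im2col +
# BLAS matmul; gradients flow back through col2im scatter-adds. This is the
# substrate for the densely connected feature extractor.

pad_hw <- function(x, p, value = 0) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(value, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[p + seq_len(d[1]), p + seq_len(d[2]), , ] <- x
  out
}

# Patch matrix [Ho*Wo*N, kh*kw*C]; column order ki-fastest, then kj, then c,
# matching the conv weight layout.
im2col <- function(xp, kh, kw, stride) {
  d <- dim(xp)
  ho <- (d[1] - kh) %/% stride + 1
  wo <- (d[2] - kw) %/% stride + 1
  out <- array(0, c(ho, wo, d[4], kh, kw, d[3]))
  for (ki in seq_len(kh)) {
    rows <- seq(ki, by = stride, length.out = ho)
    for (kj in seq_len(kw)) {
      cols <- seq(kj, by = stride, length.out = wo)
      sl <- xp[rows, cols, , , drop = FALSE] # [ho, wo, C, N]
      out[, , , ki, kj, ] <- aperm(sl, c(1, 2, 4, 3))
    }
  }
  dim(out) <- c(ho * wo * d[4], kh * kw * d[3])
  list(m = out, ho = ho, wo = wo)
}

col2im <- function(dm, hp, wp, c_in, n, kh, kw, stride, ho, wo) {
  dim(dm) <- c(ho, wo, n, kh, kw, c_in)
  dxp <- array(0, c(hp, wp, c_in, n))
  for (ki in seq_len(kh)) {
    rows <- seq(ki, by = stride, length.out = ho)
    for (kj in seq_len(kw)) {
      cols <- seq(kj, by = stride, length.out = wo)
      sl <- dm[, , , ki, kj, , drop = FALSE]
      dim(sl) <- c(ho, wo, n, c_in)
      dxp[rows, cols, , ] <- dxp[rows, cols, , ] + aperm(sl, c(1, 2, 4, 3))
    }
  }
  dxp
}

layer_conv <- function(kh, kw, c_in, c_out, stride = 1, pad = 0,
                       use_bias = FALSE) {
  # Kaiming fan-in init for ReLU networks
  w <- matrix(stats::rnorm(kh * kw * c_in * c_out, sd = sqrt(2 / (kh * kw * c_in))),
              nrow = kh * kw * c_in)
  list(type = "conv", kh = kh, kw = kw, c_in = c_in, c_out = c_out,
       stride = stride, pad = pad, W = w,
       b = if (use_bias) numeric(c_out) else NULL)
}

layer_bn <- function(c) {
  list(type = "bn", c = c, gamma = rep(1, c), beta = rep(0, c),
       running_mean = rep(0, c), running_var = rep(1, c),
       momentum = 0.1, eps = 1e-5)
}

layer_relu <- function() list(type = "relu")
layer_maxpool <- function(k = 3, stride = 2, pad = 1) {
  list(type = "maxpool", k = k, stride = stride, pad = pad)
}
layer_avgpool2 <- function() list(type = "avgpool2")

nn_forward <- function(layer, x, train = FALSE) {
  switch(layer$type,
    conv = {
      xp <- pad_hw(x, layer$pad)
      ic <- im2col(xp, layer$kh, layer$kw, layer$stride)
      y2 <- ic$m %*% layer$W
      if (!is.null(layer$b)) y2 <- y2 + rep(layer$b, each = nrow(y2))
      n <- dim(x)[4]
      dim(y2) <- c(ic$ho, ic$wo, n, layer$c_out)
      list(y = aperm(y2, c(1, 2, 4, 3)), layer = layer,
           cache = list(m = ic$m, xp_dim = dim(xp), x_dim = dim(x),
                        ho = ic$ho, wo = ic$wo))
    },
    bn = {
      d <- dim(x)
      r <- d[1] * d[2] * d[4]
      xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
      if (train) {
        mu <- colMeans(xm)
        va <- pmax(colMeans(xm^2) - mu^2, 0)
        layer$running_mean <- (1 - layer$momentum) * layer$running_mean +
          layer$momentum * mu
        layer$running_var <- (1 - layer$momentum) * layer$running_var +
          layer$momentum * va
      } else {
        mu <- layer$running_mean
        va <- layer$running_var
      }
      ivar <- 1 / sqrt(va + layer$eps)
      xhat <- (xm - rep(mu, each = r)) * rep(ivar, each = r)
      ym <- xhat * rep(layer$gamma, each = r) + rep(layer$beta, each = r)
      y <- aperm(array(ym, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      list(y = y, layer = layer,
           cache = list(xhat = xhat, ivar = ivar, dims = d, train = train))
    },
    relu = {
      mask <- x > 0
      y <- x
      y[!mask] <- 0
      list(y = y, layer = layer, cache = list(mask = mask))
    },
    maxpool = {
      xp <- pad_hw(x, layer$pad, value = -Inf)
      d <- dim(xp)
      k <- layer$k
      ho <- (d[1] - k) %/% layer$stride + 1
      wo <- (d[2] - k) %/% layer$stride + 1
      patches <- array(0, c(ho, wo, d[3], d[4], k * k))
      idx <- 0
      for (kj in seq_len(k)) {
        cols <- seq(kj, by = layer$stride, length.out = wo)
        for (ki in seq_len(k)) {
          idx <- idx + 1
          rows <- seq(ki, by = layer$stride, length.out = ho)
          patches[, , , , idx] <- xp[rows, cols, , , drop = FALSE]
        }
      }
      p2 <- matrix(patches, ncol = k * k)
      am <- max.col(p2, ties.method = "first")
      y <- array(p2[cbind(seq_len(nrow(p2)), am)], c(ho, wo, d[3], d[4]))
      list(y = y, layer = layer,
           cache = list(am = am, xp_dim = d, x_dim = dim(x), ho = ho, wo = wo))
    },
    avgpool2 = {
      d <- dim(x)
      if (d[1] %% 2 != 0 || d[2] %% 2 != 0) {
        stop("average pooling requires even spatial dimensions, got ",
             d[1], " x ", d[2], call. = FALSE)
      }
      oi <- seq(1, d[1], by = 2)
      oj <- seq(1, d[2], by = 2)
      y <- 0.25 * (x[oi, oj, , , drop = FALSE] + x[oi + 1, oj, , , drop = FALSE] +
                   x[oi, oj + 1, , , drop = FALSE] + x[oi + 1, oj + 1, , , drop = FALSE])
      dim(y) <- c(d[1] / 2, d[2] / 2, d[3], d[4])
      list(y = y, layer = layer, cache = list(x_dim = d))
    },
    stop("unknown layer type: ", layer$type)
  )
}

nn_backward <- function(layer, cache, dy) {
  switch(layer$type,
    conv = {
      n <- cache$x_dim[4]
      dy2 <- aperm(dy, c(1, 2, 4, 3))
      dim(dy2) <- c(cache$ho * cache$wo * n, layer$c_out)
      g_w <- crossprod(cache$m, dy2)
      g_b <- if (!is.null(layer$b)) colSums(dy2) else NULL
      dm <- tcrossprod(dy2, layer$W)
      dxp <- col2im(dm, cache$xp_dim[1], cache$xp_dim[2], layer$c_in, n,
                    layer$kh, layer$kw, layer$stride, cache$ho, cache$wo)
      p <- layer$pad
      dx <- if (p > 0) {
        dxp[p + seq_len(cache$x_dim[1]), p + seq_len(cache$x_dim[2]), , ,
            drop = FALSE]
      } else dxp
      dim(dx) <- cache$x_dim
      g <- list(W = g_w)
      if (!is.null(g_b)) g$b <- g_b
      list(dx = dx, grads = g)
    },
    bn = {
      d <- cache$dims
      r <- d[1] * d[2] * d[4]
      dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = d[3])
      dgamma <- colSums(dym * cache$xhat)
      dbeta <- colSums(dym)
      gi <- layer$gamma * cache$ivar
      dxm <- if (isTRUE(cache$train)) {
        (rep(gi, each = r) / r) *
          (r * dym - rep(dbeta, each = r) - cache$xhat * rep(dgamma, each = r))
      } else {
        dym * rep(gi, each = r)
      }
      dx <- aperm(array(dxm, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
    },
    relu = {
      dx <- dy
      dx[!cache$mask] <- 0
      list(dx = dx, grads = NULL)
    },
    maxpool = {
      d <- cache$xp_dim
      k <- layer$k
      npatch <- cache$ho * cache$wo * d[3] * d[4]
      r <- seq_len(npatch)
      oi <- (r - 1) %% cache$ho + 1
      oj <- ((r - 1) %/% cache$ho) %% cache$wo + 1
      cc <- ((r - 1) %/% (cache$ho * cache$wo)) %% d[3] + 1
      nn <- (r - 1) %/% (cache$ho * cache$wo * d[3]) + 1
      ki <- (cache$am - 1) %% k + 1
      kj <- (cache$am - 1) %/% k + 1
      hi <- (oi - 1) * layer$stride + ki
      wi <- (oj - 1) * layer$stride + kj
      lin <- hi + (wi - 1) * d[1] + (cc - 1) * d[1] * d[2] +
        (nn - 1) * d[1] * d[2] * d[3]
      dxp <- numeric(prod(d))
      acc <- rowsum(as.vector(dy), lin)
      dxp[as.integer(rownames(acc))] <- acc
      dim(dxp) <- d
      p <- layer$pad
      dx <- if (p > 0) {
        dxp[p + seq_len(cache$x_dim[1]), p + seq_len(cache$x_dim[2]), , ,
            drop = FALSE]
      } else dxp
      dim(dx) <- cache$x_dim
      list(dx = dx, grads = NULL)
    },
    avgpool2 = {
      d <- cache$x_dim
      dx <- array(0, d)
      oi <- seq(1, d[1], by = 2)
      oj <- seq(1, d[2], by = 2)
      q <- dy * 0.25
      dx[oi, oj, , ] <- q
      dx[oi + 1, oj, , ] <- q
      dx[oi, oj + 1, , ] <- q
      dx[oi + 1, oj + 1, , ] <- q
      list(dx = dx, grads = NULL)
    },
    stop("unknown layer type: ", layer$type)
  )
}

# ---- Adam optimizer over a parameter tree -----------------------------------
# Gradients come back as a tree with the same shape as the model (only
# trainable leaves present). State (first/second moments) mirrors the
# gradient tree.

adam_state <- function() list(t = 0, m = list())

adam_apply <- function(model, grads, state, lr = 1e-3, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  t <- state$t
  walk <- function(obj, grad, st) {
    if (is.null(grad)) return(list(obj = obj, st = st))
    if (is.numeric(grad)) {
      if (is.null(st)) st <- list(m = grad * 0, v = grad * 0)
      st$m <- beta1 * st$m + (1 - beta1) * grad
      st$v <- beta2 * st$v + (1 - beta2) * grad^2
      mhat <- st$m / (1 - beta1^t)
      vhat <- st$v / (1 - beta2^t)
      obj <- obj - lr * mhat / (sqrt(vhat) + eps)
      return(list(obj = obj, st = st))
    }
    keys <- if (is.null(names(grad))) seq_along(grad) else names(grad)
    if (is.null(st)) st <- vector("list", length(grad))
    for (nm in keys) {
      res <- walk(obj[[nm]], grad[[nm]], st[[nm]])
      obj[[nm]] <- res$obj
      st[[nm]] <- res$st
    }
    list(obj = obj, st = st)
  }
  res <- walk(model, grads, state$m)
  list(model = res$obj, state = list(t = t, m = res$st))
}

# Elementwise sum of two gradient trees (union of names).
grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.numeric(a)) return(a + b)
  keys <- if (is.null(names(a)) && is.null(names(b))) {
    seq_len(max(length(a), length(b)))
  } else union(names(a), names(b))
  for (nm in keys) a[[nm]] <- grads_add(a[[nm]], b[[nm]])
  a
}
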