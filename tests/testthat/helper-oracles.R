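# Independent oracles used across the suite.

# Welch-style averaged periodogram: frequency of maximum power.
welch_peak_freq <- function(x, fs, seg = 1024) {
  n <- length(x)
  seg <- min(seg, n)
  starts <- seq(1, n - seg + 1, by = seg %/% 2)
  pxx <- 0
  for (s in starts) {
    w <- x[s:(s + seg - 1)] * 0.5 * (1 - cos(2 * pi * seq_len(seg) / (seg + 1)))
    pxx <- pxx + Mod(stats::fft(w))^2
  }
  freqs <- (seq_len(seg) - 1) * fs / seg
  half <- freqs <= fs / 2
  freqs[half][which.max(pxx[half])]
}

# Band power via the raw periodogram.
band_power <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  p <- Mod(stats::fft(x))^2 / n
  freqs <- (seq_len(n) - 1) * fs / n
  sum(p[freqs >= f_lo & freqs <= f_hi & freqs <= fs / 2])
}

# Duplicate-implementation exact log-likelihood: brute-force sum over all
# (v, h) joint states of exp(-E(v, h)), independent of the free-energy path.
bruteforce_loglik <- function(r, data) {
  nv <- r$n_visible
  nh <- r$n_hidden
  vs <- as.matrix(expand.grid(rep(list(c(0, 1)), nv)))
  hs <- as.matrix(expand.grid(rep(list(c(0, 1)), nh)))
  energy <- function(v, h) {
    -sum(v * r$vbias) - sum(h * r$hbias) - as.numeric(t(v) %*% r$W %*% h)
  }
  pv_un <- apply(vs, 1, function(v) {
    sum(apply(hs, 1, function(h) exp(-energy(v, h))))
  })
  z <- sum(pv_un)
  mean(apply(data, 1, function(v) {
    log(sum(apply(hs, 1, function(h) exp(-energy(v, h)))) / z)
  }))
}

# Numeric gradient of the exact log-likelihood w.r.t. all RBM parameters.
numeric_loglik_grad <- function(r, data, eps = 1e-6) {
  g <- list(W = r$W * 0, vbias = r$vbias * 0, hbias = r$hbias * 0)
  for (nm in names(g)) {
    for (i in seq_along(g[[nm]])) {
      rp <- r; rp[[nm]][i] <- rp[[nm]][i] + eps
      rm <- r; rm[[nm]][i] <- rm[[nm]][i] - eps
      g[[nm]][i] <- (exact_loglik(rp, data) - exact_loglik(rm, data)) / (2 * eps)
    }
  }
  g
}

make_small_rbm <- function(nv, nh, seed = 1, sd = 0.5) {
  r <- rbm(nv, nh, seed = seed)
  set.seed(seed + 100)
  r$W <- matrix(rnorm(nv * nh, sd = sd), nv, nh)
  r$vbias <- rnorm(nv, sd = sd)
  r$hbias <- rnorm(nh, sd = sd)
  r
}
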