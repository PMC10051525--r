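# Independent brute-force oracles used to check the vectorized
# implementations, plus small shared fixtures.  Everything here is written
# as plain scalar loops on purpose: the oracle must not share code with the
# path it checks.

# Scalar-loop EvoNorm-S0: y = x * sigmoid(v x) / sqrt(GroupVar + eps) * gamma
# + beta, with the variance over (time x channels-in-group) per sample.
evonorm_s0_oracle <- function(x, gamma, beta, v, groups, eps = 1e-5) {
  d <- dim(x)
  N <- d[1]; Tt <- d[2]; C <- d[3]
  Cg <- C / groups
  out <- array(0, d)
  for (n in 1:N) {
    for (g in 1:groups) {
      chans <- ((g - 1) * Cg + 1):(g * Cg)
      vals <- c()
      for (t in 1:Tt) for (c in chans) vals <- c(vals, x[n, t, c])
      m <- mean(vals)
      va <- mean(vals^2) - m^2
      den <- sqrt(va + eps)
      for (t in 1:Tt) {
        for (c in chans) {
          xi <- x[n, t, c]
          sig <- 1 / (1 + exp(-v[c] * xi))
          out[n, t, c] <- xi * sig / den * gamma[c] + beta[c]
        }
      }
    }
  }
  out
}

# Enumeration oracle for sliding-window counts: walk the offsets one by one.
count_windows_oracle <- function(n, window, step) {
  count <- 0L
  offset <- 0L
  while (offset + window <= n) {
    count <- count + 1L
    offset <- offset + step
  }
  count
}

# Scalar one-vs-rest metric oracle from prediction/truth vectors.
metrics_oracle <- function(pred, truth, C) {
  res <- list(precision = numeric(C), recall = numeric(C), f1 = numeric(C))
  for (k in 0:(C - 1)) {
    tp <- 0; fp <- 0; fn <- 0
    for (i in seq_along(pred)) {
      if (pred[i] == k && truth[i] == k) tp <- tp + 1
      if (pred[i] == k && truth[i] != k) fp <- fp + 1
      if (pred[i] != k && truth[i] == k) fn <- fn + 1
    }
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    res$precision[k + 1] <- p
    res$recall[k + 1] <- r
    res$f1[k + 1] <- if (p + r > 0) 2 * p * r / (p + r) else 0
  }
  acc <- 0
  for (i in seq_along(pred)) if (pred[i] == truth[i]) acc <- acc + 1
  res$accuracy <- acc / length(pred)
  res
}

# A small network configuration that keeps layer tests fast.
tiny_model_config <- function(...) {
  defaults <- list(input_len = 48L, in_channels = 1L, n_classes = 3L,
                   stem_filters = 4L, stem_kernel = 3L,
                   block_filters = c(4L, 8L, 8L, 8L), block_kernel = 3L,
                   pool_size = 2L, dropout = 0, evo_groups = 2L,
                   head_hidden = 6L)
  do.call(model_config, utils::modifyList(defaults, list(...)))
}

# Central-difference gradient of a scalar-valued function of an array.
numeric_grad <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- x[i] + eps
    xm <- x; xm[i] <- x[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}
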