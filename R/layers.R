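# Differentiable 1-D network layers ------------------------------------------
#
# Activations are stored as [batch, time, channels] arrays.  Every layer has
# a forward function returning `list(out, cache)` and a backward function
# mapping the output gradient (same shape as `out`) to input and parameter
# gradients.  Convolutions are evaluated as im2col matrix products so the
# heavy lifting stays inside BLAS.

# Broadcast a per-channel vector to [N, T, C] (channel is the slowest dim).
bc_channel <- function(v, N, T, C) {
  array(rep(v, each = N * T), c(N, T, C))
}

# Broadcast an [N, C] matrix to [N, T, C].
bc_nc <- function(m, T) {
  d <- dim(m)
  out <- m[, rep(seq_len(d[2L]), each = T), drop = FALSE]
  dim(out) <- c(d[1L], T, d[2L])
  out
}

# Sum an [N, T, C] array over batch and time, giving a length-C vector.
channel_sum <- function(a) {
  d <- dim(a)
  colSums(matrix(a, d[1L] * d[2L], d[3L]))
}

# --- Conv1D -----------------------------------------------------------------
# Total padding `kernel - stride` makes the output length exactly
# floor(L / stride) for every input length (length-preserving at stride 1),
# so the two residual paths always align.

conv1d_fw <- function(x, W, b, kernel, stride = 1L) {
  d <- dim(x)
  N <- d[1L]; L <- d[2L]; Cin <- d[3L]
  pad <- kernel - stride
  pl <- pad %/% 2L
  Lp <- L + pad
  Tt <- (Lp - kernel) %/% stride + 1L
  xp <- array(0, c(N, Lp, Cin))
  xp[, pl + seq_len(L), ] <- x
  # t-fastest index order makes the im2col view reshape directly to
  # (N*T) x (kernel*Cin) without a transpose
  idx <- as.vector(outer((seq_len(Tt) - 1L) * stride, seq_len(kernel), `+`))
  xg <- xp[, idx, , drop = FALSE]
  dim(xg) <- c(N, Tt, kernel, Cin)
  dim(xg) <- c(N * Tt, kernel * Cin)
  out <- xg %*% W
  out <- sweep(out, 2L, b, `+`)
  dim(out) <- c(N, Tt, ncol(W))
  list(out = out,
       cache = list(xcol = xg, N = N, L = L, Cin = Cin, Tt = Tt,
                    kernel = kernel, stride = stride, pl = pl, Lp = Lp))
}

conv1d_bw <- function(dout, W, cache) {
  cc <- cache
  Cout <- ncol(W)
  dm <- matrix(dout, cc$N * cc$Tt, Cout)
  dW <- crossprod(cc$xcol, dm)
  db <- colSums(dm)
  dxcol <- tcrossprod(dm, W)
  dim(dxcol) <- c(cc$N, cc$Tt, cc$kernel, cc$Cin)
  dxp <- array(0, c(cc$N, cc$Lp, cc$Cin))
  for (j in seq_len(cc$kernel)) {
    pos <- (seq_len(cc$Tt) - 1L) * cc$stride + j
    dxp[, pos, ] <- dxp[, pos, , drop = FALSE] +
      array(dxcol[, , j, ], c(cc$N, cc$Tt, cc$Cin))
  }
  dx <- dxp[, cc$pl + seq_len(cc$L), , drop = FALSE]
  list(dx = dx, dW = dW, db = db)
}

# --- Max pooling (non-overlapping, remainder dropped) -----------------------

maxpool_fw <- function(x, pool = 2L) {
  d <- dim(x)
  N <- d[1L]; L <- d[2L]; C <- d[3L]
  Tt <- L %/% pool
  xt <- x[, seq_len(pool * Tt), , drop = FALSE]
  dim(xt) <- c(N, pool, Tt, C)
  out <- array(xt[, 1L, , ], c(N, Tt, C))
  arg <- array(1L, c(N, Tt, C))
  if (pool > 1L) {
    for (j in 2:pool) {
      xj <- array(xt[, j, , ], c(N, Tt, C))
      m <- xj > out
      out[m] <- xj[m]
      arg[m] <- j
    }
  }
  list(out = out, cache = list(arg = arg, N = N, L = L, C = C,
                               pool = pool, Tt = Tt))
}

maxpool_bw <- function(dout, cache) {
  cc <- cache
  dxt <- array(0, c(cc$N, cc$pool, cc$Tt, cc$C))
  for (j in seq_len(cc$pool)) {
    tmp <- array(0, c(cc$N, cc$Tt, cc$C))
    m <- cc$arg == j
    tmp[m] <- dout[m]
    dxt[, j, , ] <- tmp
  }
  dim(dxt) <- c(cc$N, cc$pool * cc$Tt, cc$C)
  dx <- array(0, c(cc$N, cc$L, cc$C))
  dx[, seq_len(cc$pool * cc$Tt), ] <- dxt
  list(dx = dx)
}

# --- ReLU and dropout -------------------------------------------------------

relu_fw <- function(x) {
  out <- x
  out[out < 0] <- 0
  list(out = out, cache = x >= 0)
}

relu_bw <- function(dout, cache) list(dx = dout * cache)

# Inverted dropout; draws from the current RNG stream (seeded by the caller).
dropout_fw <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, cache = NULL))
  mask <- array((stats::runif(length(x)) >= p) / (1 - p), dim(x))
  list(out = x * mask, cache = mask)
}

dropout_bw <- function(dout, cache) {
  if (is.null(cache)) return(list(dx = dout))
  list(dx = dout * cache)
}

# --- EvoNorm ----------------------------------------------------------------
# S0 (sample-based):  y = x * sigmoid(v x) / sqrt(GroupVar(x) + eps) * gamma + beta
# with the variance taken over (time x channels-in-group) per sample.
# B0 (batch-based, training):
#   y = x / max(sqrt(BatchVar + eps), v x + sqrt(InstVar + eps)) * gamma + beta
# with running batch variance used at inference.

# Indicator matrix mapping the (t, c) column index of matrix(x, N, T*C) to
# its channel group; X %*% ind gives per-(sample, group) sums through BLAS.
group_indicator <- function(Tt, C, groups) {
  Cg <- C %/% groups
  grp_of_col <- rep(rep(seq_len(groups), each = Cg), each = Tt)
  ind <- matrix(0, Tt * C, groups)
  ind[cbind(seq_len(Tt * C), grp_of_col)] <- 1
  ind
}

# Expand an [N, groups] matrix to [N, T, C] (group -> its channels).
bc_group <- function(m, Tt, C, groups) {
  Cg <- C %/% groups
  out <- m[, rep(rep(seq_len(groups), each = Cg), each = Tt), drop = FALSE]
  dim(out) <- c(nrow(m), Tt, C)
  out
}

evonorm_s0_fw <- function(x, gamma, beta, v, groups, eps = 1e-5) {
  d <- dim(x)
  N <- d[1L]; Tt <- d[2L]; C <- d[3L]
  if (C %% groups != 0L) {
    stop_invalid("channels (%d) not divisible by groups (%d)", C, groups)
  }
  Cg <- C %/% groups
  M <- Tt * Cg
  ind <- group_indicator(Tt, C, groups)
  X <- x
  dim(X) <- c(N, Tt * C)
  mu <- (X %*% ind) / M
  varg <- pmax((X * X) %*% ind / M - mu^2, 0)
  den_b <- bc_group(sqrt(varg + eps), Tt, C, groups)
  v_b <- bc_channel(v, N, Tt, C)
  sv <- sigmoid(v_b * x)
  u <- x * sv
  ynorm <- u / den_b
  out <- ynorm * bc_channel(gamma, N, Tt, C) + bc_channel(beta, N, Tt, C)
  list(out = out,
       cache = list(x = x, sv = sv, u = u, den_b = den_b, v_b = v_b,
                    mu = mu, varg = varg, ynorm = ynorm, ind = ind,
                    N = N, Tt = Tt, C = C, Cg = Cg, groups = groups, eps = eps))
}

evonorm_s0_bw <- function(dout, gamma, cache) {
  cc <- cache
  N <- cc$N; Tt <- cc$Tt; C <- cc$C; Cg <- cc$Cg; groups <- cc$groups
  dgamma <- channel_sum(dout * cc$ynorm)
  dbeta <- channel_sum(dout)
  Gn <- dout * bc_channel(gamma, N, Tt, C)
  Gu <- Gn / cc$den_b
  # through the group denominator
  gden_full <- -Gn * cc$u / (cc$den_b^2)
  dim(gden_full) <- c(N, Tt * C)
  S <- gden_full %*% cc$ind
  dvar <- S * 0.5 / sqrt(cc$varg + cc$eps)
  M <- Tt * Cg
  dx_var <- bc_group(dvar, Tt, C, groups) *
    2 * (cc$x - bc_group(cc$mu, Tt, C, groups)) / M
  # through the swish numerator
  dsw <- cc$sv * (1 + cc$v_b * cc$x * (1 - cc$sv))
  dx <- Gu * dsw + dx_var
  dv <- channel_sum(Gu * cc$x^2 * cc$sv * (1 - cc$sv))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta, dv = dv)
}

evonorm_b0_fw <- function(x, gamma, beta, v, eps = 1e-5, training = TRUE,
                          running_var = NULL, momentum = 0.9) {
  d <- dim(x)
  N <- d[1L]; Tt <- d[2L]; C <- d[3L]
  xm <- matrix(x, N * Tt, C)
  mu_b <- colMeans(xm)
  var_b <- pmax(colMeans(xm * xm) - mu_b^2, 0)
  if (is.null(running_var)) running_var <- var_b
  use_var <- if (training) var_b else running_var
  new_running <- if (training) momentum * running_var + (1 - momentum) * var_b else running_var
  xi <- matrix(aperm(x, c(2L, 1L, 3L)), Tt, N * C)
  mu_i <- colMeans(xi)
  var_i <- pmax(colMeans(xi * xi) - mu_i^2, 0)
  dim(mu_i) <- c(N, C)
  dim(var_i) <- c(N, C)
  a_b <- bc_channel(sqrt(use_var + eps), N, Tt, C)
  v_b <- bc_channel(v, N, Tt, C)
  b_term <- v_b * x + bc_nc(sqrt(var_i + eps), Tt)
  den <- pmax(a_b, b_term)
  y <- x / den
  out <- sweep(sweep(y, 3L, gamma, `*`), 3L, beta, `+`)
  list(out = out, running_var = new_running,
       cache = list(x = x, y = y, den = den, mask_a = a_b >= b_term,
                    v_b = v_b, mu_b = mu_b, var_b = use_var,
                    mu_i = mu_i, var_i = var_i,
                    N = N, Tt = Tt, C = C, eps = eps))
}

evonorm_b0_bw <- function(dout, gamma, cache) {
  cc <- cache
  N <- cc$N; Tt <- cc$Tt; C <- cc$C
  dgamma <- channel_sum(dout * cc$y)
  dbeta <- channel_sum(dout)
  Gn <- sweep(dout, 3L, gamma, `*`)
  dx <- Gn / cc$den
  dden <- -Gn * cc$x / (cc$den^2)
  # batch-variance branch
  dA <- dden
  dA[!cc$mask_a] <- 0
  dvar_b <- channel_sum(dA) * 0.5 / sqrt(cc$var_b + cc$eps)
  dx <- dx + bc_channel(dvar_b, N, Tt, C) *
    2 * (cc$x - bc_channel(cc$mu_b, N, Tt, C)) / (N * Tt)
  # instance branch: v x + sqrt(InstVar + eps)
  dB <- dden
  dB[cc$mask_a] <- 0
  dv <- channel_sum(dB * cc$x)
  dx <- dx + dB * cc$v_b
  dBi <- matrix(aperm(dB, c(2L, 1L, 3L)), Tt, N * C)
  dvar_i <- colSums(dBi)
  dim(dvar_i) <- c(N, C)
  dvar_i <- dvar_i * 0.5 / sqrt(cc$var_i + cc$eps)
  dx <- dx + bc_nc(dvar_i, Tt) * 2 * (cc$x - bc_nc(cc$mu_i, Tt)) / Tt
  list(dx = dx, dgamma = dgamma, dbeta = dbeta, dv = dv)
}

# --- Squeeze-and-excitation gate -------------------------------------------
# squeeze: global mean over time per channel; excitation: dense(C -> r) ->
# ReLU -> dense(r -> C) -> sigmoid; the input is rescaled per channel.

se_fw <- function(x, W1, b1, W2, b2) {
  d <- dim(x)
  N <- d[1L]; Tt <- d[2L]; C <- d[3L]
  s <- colMeans(matrix(aperm(x, c(2L, 1L, 3L)), Tt, N * C))
  dim(s) <- c(N, C)
  h_pre <- sweep(s %*% W1, 2L, b1, `+`)
  h <- pmax(h_pre, 0)
  z <- sweep(h %*% W2, 2L, b2, `+`)
  w <- sigmoid(z)
  w_b <- bc_nc(w, Tt)
  list(out = x * w_b,
       cache = list(x = x, s = s, h_pre = h_pre, h = h, w = w, w_b = w_b,
                    N = N, Tt = Tt, C = C))
}

se_bw <- function(dout, W1, W2, cache) {
  cc <- cache
  Tt <- cc$Tt
  dx <- dout * cc$w_b
  dwmat <- colSums(matrix(aperm(dout * cc$x, c(2L, 1L, 3L)), Tt, cc$N * cc$C))
  dim(dwmat) <- c(cc$N, cc$C)
  dz <- dwmat * cc$w * (1 - cc$w)
  dW2 <- crossprod(cc$h, dz)
  db2 <- colSums(dz)
  dh <- tcrossprod(dz, W2)
  dh[cc$h_pre <= 0] <- 0
  dW1 <- crossprod(cc$s, dh)
  db1 <- colSums(dh)
  ds <- tcrossprod(dh, W1)
  dx <- dx + bc_nc(ds, Tt) / Tt
  list(dx = dx, dW1 = dW1, db1 = db1, dW2 = dW2, db2 = db2)
}

# --- Dense ------------------------------------------------------------------

dense_fw <- function(x, W, b) {
  out <- sweep(x %*% W, 2L, b, `+`)
  list(out = out, cache = x)
}

dense_bw <- function(dout, W, cache) {
  list(dx = tcrossprod(dout, W),
       dW = crossprod(cache, dout),
       db = colSums(dout))
}
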