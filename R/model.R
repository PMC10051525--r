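# Network assembly: Conv1D stem -> EvoNorm -> four multiplicative residual
# blocks (each with a squeeze-and-excitation gate) -> flatten -> dense head.

#' Architectural configuration of the ECG network
#'
#' Collects every architectural free parameter.  Values stated by the method
#' are fixed defaults (SE ratio 0.25, input length 187, five classes); values
#' the method leaves open (filter counts, kernel sizes, dropout, head width)
#' are explicit defaults that can be overridden per call.
#'
#' @param input_len Input length in samples (187 for beat tasks, 3000 for the
#'   AF rhythm task).
#' @param in_channels Input channels (1 for beats, 4 for rhythm segments).
#' @param n_classes 5 (arrhythmia), 2, or 1 (single sigmoid unit for binary
#'   tasks).
#' @param stem_filters,stem_kernel Stem convolution width and kernel size.
#' @param block_filters Integer vector of length 4: output channels of the
#'   four residual blocks.
#' @param block_kernel Kernel size of the path-B convolutions.
#' @param pool_size Temporal down-sampling per block (path-A max pooling and
#'   path-B convolution stride).
#' @param dropout Dropout rate inside path B, in `[0, 1)`.
#' @param se_ratio Squeeze-and-excitation bottleneck ratio in `(0, 1]`
#'   (reduced width `max(1, round(se_ratio * C))`).
#' @param evo_variant `"S0"` (sample statistics) or `"B0"` (batch statistics).
#' @param evo_groups Group count for the S0 variance; must divide the channel
#'   count at every EvoNorm site.
#' @param use_se,use_evo,use_gc Ablation switches: disable the SE gate
#'   (identity gate), the EvoNorm layers (plain ReLU instead), or gradient
#'   clipping during training.
#' @param head_hidden Width of the hidden dense layer.
#' @return An object of class `model_config`.
#' @export
model_config <- function(input_len = 187L, in_channels = 1L, n_classes = 5L,
                         stem_filters = 32L, stem_kernel = 5L,
                         block_filters = c(64L, 128L, 192L, 256L),
                         block_kernel = 5L, pool_size = 2L, dropout = 0.1,
                         se_ratio = 0.25, evo_variant = c("S0", "B0"),
                         evo_groups = 8L, use_se = TRUE, use_evo = TRUE,
                         use_gc = TRUE, head_hidden = 64L) {
  evo_variant <- match.arg(evo_variant)
  if (length(block_filters) != 4L) stop_invalid("`block_filters` must have length 4")
  if (se_ratio <= 0 || se_ratio > 1) stop_invalid("`se_ratio` must lie in (0, 1]")
  if (dropout < 0 || dropout >= 1) stop_invalid("`dropout` must lie in [0, 1)")
  L <- as.integer(input_len)
  lens <- integer(4L)
  for (k in 1:4) {
    L <- L %/% pool_size
    lens[k] <- L
  }
  if (L < 1L) stop_invalid("input_len %d too short to survive 4 poolings", input_len)
  if (use_evo && evo_variant == "S0") {
    widths <- c(stem_filters, block_filters[1:3])
    bad <- widths[widths %% evo_groups != 0L]
    if (length(bad)) {
      stop_invalid("evo_groups (%d) must divide every normalized channel width (violated by %s)",
                   evo_groups, paste(bad, collapse = ", "))
    }
  }
  structure(list(input_len = as.integer(input_len),
                 in_channels = as.integer(in_channels),
                 n_classes = as.integer(n_classes),
                 stem_filters = as.integer(stem_filters),
                 stem_kernel = as.integer(stem_kernel),
                 block_filters = as.integer(block_filters),
                 block_kernel = as.integer(block_kernel),
                 pool_size = as.integer(pool_size),
                 dropout = dropout, se_ratio = se_ratio,
                 evo_variant = evo_variant, evo_groups = as.integer(evo_groups),
                 use_se = use_se, use_evo = use_evo, use_gc = use_gc,
                 head_hidden = as.integer(head_hidden),
                 block_lens = lens),
            class = "model_config")
}

# Fan-in scaled uniform initialization, U(-sqrt(6/fan_in), +sqrt(6/fan_in));
# draws from the current RNG stream.
init_mat <- function(nr, nc, fan_in) {
  matrix(stats::runif(nr * nc, -sqrt(6 / fan_in), sqrt(6 / fan_in)), nr, nc)
}

se_reduced_width <- function(C, ratio) max(1L, as.integer(round(ratio * C)))

#' Build the network
#'
#' Instantiates all trainable parameters (seeded, fan-in scaled uniform) and
#' returns the model together with a parameter-count report.
#'
#' @param cfg A [model_config()].
#' @param seed RNG seed for weight initialization.
#' @return An object of class `ecg_model`: list with `cfg`, `params` (flat
#'   named list of arrays), `state` (running statistics for the B0 variant)
#'   and `n_params`.
#' @examples
#' m <- build_model(model_config(), seed = 1)
#' x <- array(stats::runif(2 * 187), c(2, 187, 1))
#' p <- model_forward(m, x)$probs   # 2 x 5, rows sum to 1
#' @export
build_model <- function(cfg, seed = 0L) {
  stopifnot(inherits(cfg, "model_config"))
  with_seed(seed, {
    p <- list()
    add_norm <- function(p, name, C) {
      if (!cfg$use_evo) return(p)
      p[[paste0(name, ".gamma")]] <- rep(1, C)
      p[[paste0(name, ".beta")]] <- rep(0, C)
      p[[paste0(name, ".v")]] <- rep(1, C)
      p
    }
    p[["stem.W"]] <- init_mat(cfg$stem_kernel * cfg$in_channels, cfg$stem_filters,
                              cfg$stem_kernel * cfg$in_channels)
    p[["stem.b"]] <- rep(0, cfg$stem_filters)
    p <- add_norm(p, "stem_norm", cfg$stem_filters)
    cin <- cfg$stem_filters
    for (k in 1:4) {
      cout <- cfg$block_filters[k]
      nm <- paste0("block", k)
      p[[paste0(nm, ".A.W")]] <- init_mat(cin, cout, cin)
      p[[paste0(nm, ".A.b")]] <- rep(0, cout)
      p <- add_norm(p, paste0(nm, ".norm"), cin)
      p[[paste0(nm, ".B.W")]] <- init_mat(cfg$block_kernel * cin, cout,
                                          cfg$block_kernel * cin)
      p[[paste0(nm, ".B.b")]] <- rep(0, cout)
      if (cfg$use_se) {
        r <- se_reduced_width(cout, cfg$se_ratio)
        p[[paste0(nm, ".se.W1")]] <- init_mat(cout, r, cout)
        p[[paste0(nm, ".se.b1")]] <- rep(0, r)
        p[[paste0(nm, ".se.W2")]] <- init_mat(r, cout, r)
        p[[paste0(nm, ".se.b2")]] <- rep(0, cout)
      }
      cin <- cout
    }
    flat <- cfg$block_lens[4L] * cfg$block_filters[4L]
    p[["head1.W"]] <- init_mat(flat, cfg$head_hidden, flat)
    p[["head1.b"]] <- rep(0, cfg$head_hidden)
    p[["out.W"]] <- init_mat(cfg$head_hidden, cfg$n_classes, cfg$head_hidden)
    p[["out.b"]] <- rep(0, cfg$n_classes)
    state <- list()
    if (cfg$use_evo && cfg$evo_variant == "B0") {
      state[["stem_norm.running_var"]] <- NULL
      for (k in 1:4) state[[paste0("block", k, ".norm.running_var")]] <- NULL
    }
    structure(list(cfg = cfg, params = p, state = state,
                   n_params = sum(vapply(p, length, integer(1)))),
              class = "ecg_model")
  })
}

#' @export
print.ecg_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf("<ecg_model> input %d x %d -> %d class%s; %s parameters\n",
              cfg$input_len, cfg$in_channels, cfg$n_classes,
              if (cfg$n_classes == 1L) " (sigmoid)" else "es",
              format(x$n_params, big.mark = ",")))
  cat(sprintf("  stem %d@%d | blocks %s@%d pool %d | EvoNorm %s (%s) | SE %s (ratio %.2f) | head %d\n",
              cfg$stem_filters, cfg$stem_kernel,
              paste(cfg$block_filters, collapse = "-"), cfg$block_kernel,
              cfg$pool_size,
              if (cfg$use_evo) "on" else "off", cfg$evo_variant,
              if (cfg$use_se) "on" else "off", cfg$se_ratio, cfg$head_hidden))
  invisible(x)
}

# Normalization-activation site: EvoNorm when enabled, plain ReLU otherwise.
norm_act_fw <- function(x, model, name, training) {
  cfg <- model$cfg
  if (!cfg$use_evo) {
    r <- relu_fw(x)
    return(list(out = r$out, cache = list(kind = "relu", c = r$cache),
                state = NULL))
  }
  p <- model$params
  if (cfg$evo_variant == "S0") {
    r <- evonorm_s0_fw(x, p[[paste0(name, ".gamma")]], p[[paste0(name, ".beta")]],
                       p[[paste0(name, ".v")]], cfg$evo_groups)
    list(out = r$out, cache = list(kind = "s0", c = r$cache), state = NULL)
  } else {
    r <- evonorm_b0_fw(x, p[[paste0(name, ".gamma")]], p[[paste0(name, ".beta")]],
                       p[[paste0(name, ".v")]], training = training,
                       running_var = model$state[[paste0(name, ".running_var")]])
    list(out = r$out, cache = list(kind = "b0", c = r$cache),
         state = r$running_var)
  }
}

norm_act_bw <- function(dout, model, name, cache) {
  if (cache$kind == "relu") {
    return(list(dx = relu_bw(dout, cache$c)$dx, grads = list()))
  }
  g <- model$params[[paste0(name, ".gamma")]]
  r <- if (cache$kind == "s0") evonorm_s0_bw(dout, g, cache$c)
       else evonorm_b0_bw(dout, g, cache$c)
  grads <- list(r$dgamma, r$dbeta, r$dv)
  names(grads) <- paste0(name, c(".gamma", ".beta", ".v"))
  list(dx = r$dx, grads = grads)
}

#' Forward pass
#'
#' @param model An [build_model()] result.
#' @param x `[batch, input_len, in_channels]` array (a plain n x L matrix is
#'   promoted to a single channel).
#' @param training Logical; enables dropout and batch statistics.
#' @param keep_cache Keep layer caches for [model_backward()].
#' @return List with `logits` (batch x n_classes), `probs` (softmax rows for
#'   multi-class, sigmoid for a single unit), `caches` (when requested) and
#'   `state` (updated running statistics).
#' @export
model_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cfg <- model$cfg
  p <- model$params
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  d <- dim(x)
  if (d[2L] != cfg$input_len || d[3L] != cfg$in_channels) {
    stop_invalid("input must be [batch, %d, %d]; got [%s]",
                 cfg$input_len, cfg$in_channels, paste(d, collapse = ", "))
  }
  caches <- list()
  state <- model$state
  st <- conv1d_fw(x, p[["stem.W"]], p[["stem.b"]], cfg$stem_kernel, 1L)
  caches$stem <- st$cache
  na <- norm_act_fw(st$out, model, "stem_norm", training)
  if (!is.null(na$state)) state[["stem_norm.running_var"]] <- na$state
  caches$stem_norm <- na$cache
  h <- na$out
  for (k in 1:4) {
    nm <- paste0("block", k)
    bc <- list()
    # path A: max pool -> 1x1 conv projection
    mp <- maxpool_fw(h, cfg$pool_size)
    bc$pool <- mp$cache
    pa <- conv1d_fw(mp$out, p[[paste0(nm, ".A.W")]], p[[paste0(nm, ".A.b")]], 1L, 1L)
    bc$convA <- pa$cache
    # path B: norm-act -> dropout -> strided conv -> SE gate
    nb <- norm_act_fw(h, model, paste0(nm, ".norm"), training)
    if (!is.null(nb$state)) state[[paste0(nm, ".norm.running_var")]] <- nb$state
    bc$norm <- nb$cache
    dr <- dropout_fw(nb$out, cfg$dropout, training)
    bc$drop <- dr$cache
    pb <- conv1d_fw(dr$out, p[[paste0(nm, ".B.W")]], p[[paste0(nm, ".B.b")]],
                    cfg$block_kernel, cfg$pool_size)
    bc$convB <- pb$cache
    outB <- pb$out
    if (cfg$use_se) {
      se <- se_fw(outB, p[[paste0(nm, ".se.W1")]], p[[paste0(nm, ".se.b1")]],
                  p[[paste0(nm, ".se.W2")]], p[[paste0(nm, ".se.b2")]])
      bc$se <- se$cache
      outB <- se$out
    }
    stopifnot(identical(dim(pa$out), dim(outB)))
    bc$a_out <- pa$out
    bc$b_out <- outB
    h <- pa$out * outB  # multiplicative merge of the two paths
    caches[[nm]] <- bc
  }
  N <- dim(h)[1L]
  hf <- matrix(h, N, prod(dim(h)[2:3]))
  caches$flat_dim <- dim(h)
  d1 <- dense_fw(hf, p[["head1.W"]], p[["head1.b"]])
  caches$head1 <- d1$cache
  r1 <- relu_fw(d1$out)
  caches$head1_relu <- r1$cache
  d2 <- dense_fw(r1$out, p[["out.W"]], p[["out.b"]])
  caches$out <- d2$cache
  logits <- d2$out
  probs <- if (cfg$n_classes == 1L) {
    sigmoid(logits)
  } else {
    e <- exp(logits - apply(logits, 1L, max))
    e / rowSums(e)
  }
  list(logits = logits, probs = probs,
       caches = if (keep_cache) caches else NULL, state = state)
}

#' Backward pass
#'
#' Maps the gradient of the loss with respect to the logits back to every
#' trainable parameter.
#'
#' @param model The model used in [model_forward()].
#' @param caches Caches from `model_forward(..., keep_cache = TRUE)`.
#' @param dlogits Gradient at the logits, batch x n_classes.
#' @return Flat named list of gradients matching `model$params`.
#' @export
model_backward <- function(model, caches, dlogits) {
  cfg <- model$cfg
  p <- model$params
  g <- list()
  d2 <- dense_bw(dlogits, p[["out.W"]], caches$out)
  g[["out.W"]] <- d2$dW; g[["out.b"]] <- d2$db
  dr1 <- relu_bw(d2$dx, caches$head1_relu)$dx
  d1 <- dense_bw(dr1, p[["head1.W"]], caches$head1)
  g[["head1.W"]] <- d1$dW; g[["head1.b"]] <- d1$db
  dh <- array(d1$dx, caches$flat_dim)
  for (k in 4:1) {
    nm <- paste0("block", k)
    bc <- caches[[nm]]
    dA <- dh * bc$b_out
    dB <- dh * bc$a_out
    if (cfg$use_se) {
      se <- se_bw(dB, p[[paste0(nm, ".se.W1")]], p[[paste0(nm, ".se.W2")]], bc$se)
      g[[paste0(nm, ".se.W1")]] <- se$dW1; g[[paste0(nm, ".se.b1")]] <- se$db1
      g[[paste0(nm, ".se.W2")]] <- se$dW2; g[[paste0(nm, ".se.b2")]] <- se$db2
      dB <- se$dx
    }
    cb <- conv1d_bw(dB, p[[paste0(nm, ".B.W")]], bc$convB)
    g[[paste0(nm, ".B.W")]] <- cb$dW; g[[paste0(nm, ".B.b")]] <- cb$db
    ddr <- dropout_bw(cb$dx, bc$drop)$dx
    nb <- norm_act_bw(ddr, model, paste0(nm, ".norm"), bc$norm)
    g[names(nb$grads)] <- nb$grads
    dxB <- nb$dx
    ca <- conv1d_bw(dA, p[[paste0(nm, ".A.W")]], bc$convA)
    g[[paste0(nm, ".A.W")]] <- ca$dW; g[[paste0(nm, ".A.b")]] <- ca$db
    dxA <- maxpool_bw(ca$dx, bc$pool)$dx
    dh <- dxA + dxB
  }
  ns <- norm_act_bw(dh, model, "stem_norm", caches$stem_norm)
  g[names(ns$grads)] <- ns$grads
  cs <- conv1d_bw(ns$dx, p[["stem.W"]], caches$stem)
  g[["stem.W"]] <- cs$dW; g[["stem.b"]] <- cs$db
  g[names(model$params)]
}

#' Predict class probabilities and labels
#'
#' @param model A trained [build_model()] object.
#' @param x Input array/matrix or a [beat_dataset()] / [segment_dataset()].
#' @param batch_size Mini-batch size used for the forward passes.
#' @return List with `probs` and `pred` (0-based class ids; threshold 0.5 for
#'   a single sigmoid unit).
#' @export
predict_model <- function(model, x, batch_size = 256L) {
  if (inherits(x, "beat_dataset")) x <- x$beats
  if (inherits(x, "segment_dataset")) x <- x$segments
  if (is.matrix(x)) x <- array(x, c(nrow(x), ncol(x), 1L))
  n <- dim(x)[1L]
  probs <- NULL
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    pr <- model_forward(model, x[s:e, , , drop = FALSE])$probs
    probs <- rbind(probs, pr)
  }
  pred <- if (model$cfg$n_classes == 1L) as.integer(probs[, 1L] > 0.5)
          else max.col(probs) - 1L
  list(probs = probs, pred = pred)
}

#' Parameter-count report by component
#'
#' @param model An `ecg_model`.
#' @return Named integer vector of parameter counts per component plus a
#'   `total`.
#' @export
param_count_report <- function(model) {
  nm <- names(model$params)
  comp <- sub("\\..*$", "", nm)
  counts <- vapply(split(vapply(model$params, length, integer(1)), comp), sum,
                   integer(1))
  c(counts, total = model$n_params)
}
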