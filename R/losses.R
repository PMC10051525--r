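# Training objectives: categorical cross-entropy, binary focal loss, and
# binary cross-entropy.  Scalar forms are exported; batch forms with analytic
# logit gradients (mean reduction) are used by the training loop.

PROB_EPS <- 1e-7

clamp_prob <- function(p) pmin(pmax(p, PROB_EPS), 1 - PROB_EPS)

#' Categorical cross-entropy from raw scores
#'
#' `CE = -log( exp(s_p) / sum_j exp(s_j) )`, evaluated through the
#' log-sum-exp stable form, so it is safe for large scores.
#'
#' @param scores Numeric vector of C pre-softmax scores, or an n x C matrix.
#' @param p_index 0-based index of the positive class (matching the
#'   package's 0-based class ids); a vector of length n for matrix input.
#' @return Nonnegative loss value(s).
#' @export
categorical_cross_entropy <- function(scores, p_index) {
  if (is.matrix(scores)) {
    stopifnot(length(p_index) == nrow(scores))
    mx <- apply(scores, 1L, max)
    lse <- mx + log(rowSums(exp(scores - mx)))
    sp <- scores[cbind(seq_len(nrow(scores)), as.integer(p_index) + 1L)]
    return(lse - sp)
  }
  if (p_index < 0 || p_index >= length(scores)) {
    stop_invalid("`p_index` must lie in [0, %d)", length(scores))
  }
  mx <- max(scores)
  (mx + log(sum(exp(scores - mx)))) - scores[p_index + 1L]
}

#' Binary focal loss
#'
#' `FL(p_t) = -alpha_t * (1 - p_t)^gamma * log(p_t)` with `p_t = p` for
#' `y = 1` and `1 - p` for `y = 0`; probabilities are clamped to
#' `[1e-7, 1 - 1e-7]`.  With `gamma = 0, alpha_t = 1` this reduces exactly to
#' binary cross-entropy.  Defaults are the method's settings
#' (`alpha_t = 0.25`, `gamma = 2`).
#'
#' @param p Predicted probability(ies) of the positive class.
#' @param y Observed label(s) in `{0, 1}`.
#' @param alpha_t Weighting factor in `(0, 1]`.
#' @param gamma Focusing exponent `>= 0`.
#' @return Nonnegative loss value(s), vectorized over `p`/`y`.
#' @export
binary_focal_loss <- function(p, y, alpha_t = 0.25, gamma = 2) {
  if (alpha_t <= 0 || alpha_t > 1) stop_invalid("`alpha_t` must lie in (0, 1]")
  if (gamma < 0) stop_invalid("`gamma` must be >= 0")
  p <- clamp_prob(p)
  pt <- ifelse(y == 1, p, 1 - p)
  -alpha_t * (1 - pt)^gamma * log(pt)
}

#' Binary cross-entropy
#'
#' `-[y log p + (1 - y) log(1 - p)]` with the same probability clamping as
#' [binary_focal_loss()].
#'
#' @inheritParams binary_focal_loss
#' @return Nonnegative loss value(s).
#' @export
binary_cross_entropy <- function(p, y) {
  p <- clamp_prob(p)
  -(y * log(p) + (1 - y) * log(1 - p))
}

# --- batch losses at the logits (mean reduction + gradient) -----------------

softmax_ce_batch <- function(logits, labels) {
  n <- nrow(logits)
  e <- exp(logits - apply(logits, 1L, max))
  probs <- e / rowSums(e)
  idx <- cbind(seq_len(n), as.integer(labels) + 1L)
  loss <- mean(-log(pmax(probs[idx], PROB_EPS)))
  dlogits <- probs
  dlogits[idx] <- dlogits[idx] - 1
  list(loss = loss, dlogits = dlogits / n, probs = probs)
}

sigmoid_focal_batch <- function(logits, y, alpha_t = 0.25, gamma = 2) {
  n <- length(y)
  p <- clamp_prob(sigmoid(logits[, 1L]))
  pt <- ifelse(y == 1, p, 1 - p)
  loss <- mean(-alpha_t * (1 - pt)^gamma * log(pt))
  # dFL/dpt, then dpt/dz = +/- p(1-p)
  dpt <- alpha_t * gamma * (1 - pt)^(gamma - 1) * log(pt) -
    alpha_t * (1 - pt)^gamma / pt
  dz <- dpt * ifelse(y == 1, 1, -1) * p * (1 - p)
  list(loss = loss, dlogits = matrix(dz / n, ncol = 1L), probs = p)
}

sigmoid_bce_batch <- function(logits, y) {
  p <- clamp_prob(sigmoid(logits[, 1L]))
  loss <- mean(-(y * log(p) + (1 - y) * log(1 - p)))
  list(loss = loss, dlogits = matrix((p - y) / length(y), ncol = 1L), probs = p)
}
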