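# Layer-level numerics: the EvoNorm oracle, SE contracts, and
# finite-difference gradient checks for every backward pass.

test_that("EvoNorm-S0 matches the scalar-loop oracle on random tensors", {
  set.seed(101)
  for (i in 1:100) {
    N <- sample(1:3, 1); Tt <- sample(2:6, 1)
    groups <- sample(1:2, 1); C <- groups * sample(1:3, 1)
    x <- array(rnorm(N * Tt * C), c(N, Tt, C))
    gamma <- runif(C, 0.5, 1.5); beta <- rnorm(C); v <- rnorm(C)
    got <- ecgnet:::evonorm_s0_fw(x, gamma, beta, v, groups)$out
    want <- evonorm_s0_oracle(x, gamma, beta, v, groups)
    expect_lt(max(abs(got - want)), 1e-6)
  }
})

test_that("EvoNorm-S0 on zero input returns beta and errors on bad groups", {
  x <- array(0, c(2, 5, 4))
  beta <- c(1, -2, 3, 0.5)
  out <- ecgnet:::evonorm_s0_fw(x, rep(1, 4), beta, rep(1, 4), 2)$out
  for (c in 1:4) expect_true(all(out[, , c] == beta[c]))
  expect_error(ecgnet:::evonorm_s0_fw(x, rep(1, 4), beta, rep(1, 4), 3),
               "divisible")
})

test_that("EvoNorm-S0 output is bounded by the normalized input", {
  set.seed(5)
  x <- array(rnorm(60), c(2, 5, 6))
  fw <- ecgnet:::evonorm_s0_fw(x, rep(1, 6), rep(0, 6), rep(1, 6), 2)
  expect_true(all(abs(fw$out) <= abs(x) / fw$cache$den_b + 1e-12))
})

test_that("EvoNorm backward passes match finite differences", {
  set.seed(7)
  x <- array(rnorm(2 * 6 * 4), c(2, 6, 4))
  gamma <- runif(4, .5, 1.5); beta <- rnorm(4); v <- rnorm(4)
  G <- array(rnorm(length(x)), dim(x))

  fw <- ecgnet:::evonorm_s0_fw(x, gamma, beta, v, 2)
  bw <- ecgnet:::evonorm_s0_bw(G, gamma, fw$cache)
  f <- function(xx) sum(G * ecgnet:::evonorm_s0_fw(xx, gamma, beta, v, 2)$out)
  idx <- sample(length(x), 12)
  expect_lt(max(abs(numeric_grad(f, x, idx) - bw$dx[idx])), 1e-5)
  fg <- function(gg) sum(G * ecgnet:::evonorm_s0_fw(x, gg, beta, v, 2)$out)
  expect_lt(max(abs(numeric_grad(fg, gamma, 1:4) - bw$dgamma)), 1e-5)
  fv <- function(vv) sum(G * ecgnet:::evonorm_s0_fw(x, gamma, beta, vv, 2)$out)
  expect_lt(max(abs(numeric_grad(fv, v, 1:4) - bw$dv)), 1e-5)

  fwb <- ecgnet:::evonorm_b0_fw(x, gamma, beta, v, training = TRUE)
  bwb <- ecgnet:::evonorm_b0_bw(G, gamma, fwb$cache)
  fb <- function(xx) sum(G * ecgnet:::evonorm_b0_fw(xx, gamma, beta, v,
                                                    training = TRUE)$out)
  expect_lt(max(abs(numeric_grad(fb, x, idx) - bwb$dx[idx])), 1e-4)
})

test_that("EvoNorm-B0 running statistics drive inference", {
  set.seed(9)
  x <- array(rnorm(2 * 5 * 3, sd = 2), c(2, 5, 3))
  gamma <- rep(1, 3); beta <- rep(0, 3); v <- rep(1, 3)
  tr <- ecgnet:::evonorm_b0_fw(x, gamma, beta, v, training = TRUE)
  inf <- ecgnet:::evonorm_b0_fw(x, gamma, beta, v, training = FALSE,
                                running_var = tr$running_var)
  expect_equal(dim(inf$out), dim(x))
  expect_true(all(is.finite(inf$out)))
  # running update blends old and new batch variance (momentum 0.9)
  tr2 <- ecgnet:::evonorm_b0_fw(x * 3, gamma, beta, v, training = TRUE,
                                running_var = tr$running_var)
  xm <- matrix(x * 3, 10, 3)
  vb <- colMeans(xm^2) - colMeans(xm)^2
  expect_equal(tr2$running_var, 0.9 * tr$running_var + 0.1 * vb)
})

test_that("SE block honors its zero-parameter and reduced-width contracts", {
  set.seed(13)
  C <- 8L
  x <- array(rnorm(2 * 5 * C), c(2, 5, C))
  r <- ecgnet:::se_reduced_width(C, 0.25)
  expect_equal(r, 2L)
  for (Ck in c(4L, 8L, 16L, 32L)) {
    expect_equal(ecgnet:::se_reduced_width(Ck, 0.25), as.integer(round(0.25 * Ck)))
  }
  zero <- ecgnet:::se_fw(x, matrix(0, C, r), rep(0, r), matrix(0, r, C), rep(0, C))
  expect_equal(zero$out, 0.5 * x)  # sigmoid(0) = 0.5 gate
  # +20 bias on the second dense ~ identity gate
  ident <- ecgnet:::se_fw(x, matrix(0, C, r), rep(0, r), matrix(0, r, C), rep(20, C))
  expect_lt(max(abs(ident$out - x)), 1e-6)
  # gates lie strictly inside (0, 1): |y| < |x| wherever x != 0
  W1 <- matrix(rnorm(C * r), C, r); W2 <- matrix(rnorm(r * C), r, C)
  fw <- ecgnet:::se_fw(x, W1, rnorm(r), W2, rnorm(C))
  nz <- x != 0
  expect_true(all(abs(fw$out[nz]) < abs(x[nz])))
})

test_that("SE backward matches finite differences", {
  set.seed(17)
  C <- 4L; r <- 2L
  x <- array(rnorm(2 * 5 * C), c(2, 5, C))
  W1 <- matrix(rnorm(C * r, sd = .5), C, r); b1 <- rnorm(r)
  W2 <- matrix(rnorm(r * C, sd = .5), r, C); b2 <- rnorm(C)
  G <- array(rnorm(length(x)), dim(x))
  fw <- ecgnet:::se_fw(x, W1, b1, W2, b2)
  bw <- ecgnet:::se_bw(G, W1, W2, fw$cache)
  f <- function(xx) sum(G * ecgnet:::se_fw(xx, W1, b1, W2, b2)$out)
  idx <- sample(length(x), 10)
  expect_lt(max(abs(numeric_grad(f, x, idx) - bw$dx[idx])), 1e-5)
  fW1 <- function(w) sum(G * ecgnet:::se_fw(x, w, b1, W2, b2)$out)
  expect_lt(max(abs(numeric_grad(fW1, W1, seq_along(W1)) - bw$dW1)), 1e-5)
  fW2 <- function(w) sum(G * ecgnet:::se_fw(x, W1, b1, w, b2)$out)
  expect_lt(max(abs(numeric_grad(fW2, W2, seq_along(W2)) - bw$dW2)), 1e-5)
})

test_that("conv1d output length is floor(L/stride) and gradients are exact", {
  set.seed(19)
  for (case in list(c(L = 17, k = 5, s = 2), c(L = 16, k = 5, s = 2),
                    c(L = 12, k = 3, s = 1), c(L = 11, k = 1, s = 1))) {
    L <- unname(case["L"]); k <- unname(case["k"]); s <- unname(case["s"])
    x <- array(rnorm(2 * L * 3), c(2, L, 3))
    W <- matrix(rnorm(k * 3 * 4, sd = .3), k * 3, 4)
    b <- rnorm(4)
    fw <- ecgnet:::conv1d_fw(x, W, b, k, s)
    expect_equal(dim(fw$out), c(2L, as.integer(L %/% s), 4L))
    G <- array(rnorm(length(fw$out)), dim(fw$out))
    bw <- ecgnet:::conv1d_bw(G, W, fw$cache)
    f <- function(xx) sum(G * ecgnet:::conv1d_fw(xx, W, b, k, s)$out)
    idx <- sample(length(x), 8)
    expect_lt(max(abs(numeric_grad(f, x, idx) - bw$dx[idx])), 1e-5)
    fW <- function(w) sum(G * ecgnet:::conv1d_fw(x, w, b, k, s)$out)
    iW <- sample(length(W), 8)
    expect_lt(max(abs(numeric_grad(fW, W, iW) - bw$dW[iW])), 1e-5)
  }
})

test_that("maxpool backward routes gradient to the argmax", {
  set.seed(23)
  x <- array(rnorm(2 * 9 * 3), c(2, 9, 3))
  fw <- ecgnet:::maxpool_fw(x, 2L)
  expect_equal(dim(fw$out), c(2L, 4L, 3L))
  G <- array(rnorm(length(fw$out)), dim(fw$out))
  bw <- ecgnet:::maxpool_bw(G, fw$cache)
  f <- function(xx) sum(G * ecgnet:::maxpool_fw(xx, 2L)$out)
  idx <- sample(length(x), 15)
  expect_lt(max(abs(numeric_grad(f, x, idx) - bw$dx[idx])), 1e-6)
  # the dropped remainder sample receives zero gradient
  expect_true(all(bw$dx[, 9, ] == 0))
})
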