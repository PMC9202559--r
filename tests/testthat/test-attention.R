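# brute-force scalar-loop oracle for the attention gate
attention_oracle <- function(e, o, U, W, V) {
  n <- nrow(e)
  s <- numeric(n)
  for (j in seq_len(n))
    s[j] <- sum(V * tanh(as.numeric(U %*% e[j, ]) + as.numeric(W %*% o[j, ])))
  a <- exp(s - max(s)); a <- a / sum(a)
  ctx <- numeric(ncol(e))
  for (j in seq_len(n)) ctx <- ctx + a[j] * e[j, ]
  list(alpha = a, context = ctx)
}

test_that("attention weights are a proper distribution on random inputs", {
  set.seed(10)
  for (trial in 1:5) {
    ce <- sample(2:6, 1); cd <- sample(2:6, 1); m <- sample(2:5, 1)
    p <- attention_gate_params(matrix(rnorm(ce * m), ce, m),
                               matrix(rnorm(cd * m), cd, m), rnorm(m))
    e <- array(rnorm(6 * 5 * ce), dim = c(6, 5, ce))
    o <- array(rnorm(6 * 5 * cd), dim = c(6, 5, cd))
    r <- attention_gate(e, o, p)
    expect_true(all(r$alphas >= 0))
    expect_lt(abs(sum(r$alphas) - 1), 1e-6)
    # context lies in the convex hull of the features, per channel
    em <- matrix(e, 30, ce)
    expect_true(all(r$context >= apply(em, 2, min) - 1e-12 &
                      r$context <= apply(em, 2, max) + 1e-12))
  }
})

test_that("zero transforms give uniform attention", {
  ce <- 3L; cd <- 2L; m <- 4L
  p <- attention_gate_params(matrix(0, ce, m), matrix(0, cd, m), rnorm(m))
  e <- array(rnorm(4 * 4 * ce), dim = c(4, 4, ce))
  o <- array(rnorm(4 * 4 * cd), dim = c(4, 4, cd))
  r <- attention_gate(e, o, p)
  expect_equal(as.vector(r$alphas), rep(1 / 16, 16), tolerance = 1e-12)
  # uniform alpha makes the gated skip the identity
  expect_equal(r$gated, e, tolerance = 1e-12)
})

test_that("a one-hot alpha returns that location's feature as the context", {
  # score +50 at location k, -50 elsewhere, via a crafted e and direct scores
  e <- matrix(rnorm(8), 4, 2)
  o <- matrix(0, 4, 1)
  # U maps channel 1 to the score; engineer e so location 3 dominates
  e[, 1] <- c(-50, -50, 50, -50) / 25
  p <- attention_gate_params(U = matrix(c(25, 0), 2, 1), W = matrix(0, 1, 1),
                             V = 60)   # V * tanh(25 * e1): +-~60
  r <- attention_gate(e, o, p)
  expect_equal(r$context, e[3, ], tolerance = 1e-6)
})

test_that("attention matches the scalar-loop oracle on random 2x2 maps", {
  set.seed(11)
  for (trial in 1:10) {
    ce <- 3L; cd <- 2L; m <- 3L
    U <- matrix(rnorm(ce * m), ce, m); W <- matrix(rnorm(cd * m), cd, m)
    V <- rnorm(m)
    e <- matrix(rnorm(4 * ce), 4, ce); o <- matrix(rnorm(4 * cd), 4, cd)
    r <- attention_gate(e, o, attention_gate_params(U, W, V))
    orc <- attention_oracle(e, o, t(U), t(W), V)
    expect_equal(as.vector(r$alphas), orc$alpha, tolerance = 1e-6)
    expect_equal(r$context, orc$context, tolerance = 1e-6)
  }
})

test_that("alpha is invariant to a constant score shift", {
  # adding a constant to all scores leaves the softmax unchanged; emulate
  # by shifting V's output through an extra tanh-saturated channel
  set.seed(12)
  e <- matrix(rnorm(9 * 3), 9, 3)
  o <- matrix(rnorm(9 * 2), 9, 2)
  U <- matrix(rnorm(6), 3, 2); W <- matrix(rnorm(4), 2, 2); V <- rnorm(2)
  base <- attention_gate(e, o, attention_gate_params(U, W, V))
  # augment with a tanh-saturated constant channel: every score shifts by
  # the same V2[3] * tanh(1000) ~ V2[3]
  e2 <- cbind(e, 1000)
  U2 <- rbind(cbind(U, 0), c(0, 0, 1))
  W2 <- cbind(W, 0)
  V2 <- c(V, 5)
  shifted <- attention_gate(e2, o, attention_gate_params(U2, W2, V2))
  expect_equal(shifted$alphas, base$alphas, tolerance = 1e-9)
})

test_that("spatial misalignment is a contract error", {
  p <- attention_gate_params(matrix(1, 2, 2), matrix(1, 2, 2), c(1, 1))
  e <- array(rnorm(4 * 4 * 2), dim = c(4, 4, 2))
  o <- array(rnorm(3 * 3 * 2), dim = c(3, 3, 2))
  expect_error(attention_gate(e, o, p), class = "attnseg_contract_error")
})
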