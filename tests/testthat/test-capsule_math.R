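test_that("squash matches its closed form and preserves direction", {
  # hand-derived: s = (3,4), ||s|| = 5, v = (25/26)*(0.6, 0.8)
  v <- squash(c(3, 4))
  expect_equal(v, (25 / 26) * c(0.6, 0.8), tolerance = 1e-12)
  expect_equal(sqrt(sum(v^2)), 25 / 26, tolerance = 1e-12)

  expect_equal(squash(c(0, 0, 0)), c(0, 0, 0))
  expect_error(squash(c(1, NA)), "non-finite")

  set.seed(1)
  for (rep in 1:50) {
    s <- rnorm(sample(1:6, 1))
    v <- squash(s)
    expect_equal(v, squash_oracle(s), tolerance = 1e-9)  # eps guard in ||s||
    expect_lt(sqrt(sum(v^2)), 1)
    if (sqrt(sum(s^2)) > 1e-8) {
      cosine <- sum(s * v) / sqrt(sum(s^2) * sum(v^2))
      expect_equal(cosine, 1, tolerance = 1e-9)
    }
  }
  # length approaches 1 monotonically as the input grows
  lens <- sapply(c(1, 10, 100, 1000), function(t) sqrt(sum(squash(t * c(1, 0))^2)))
  expect_true(all(diff(lens) > 0))
  expect_lt(max(lens), 1)
})

test_that("prediction vectors match an element-wise loop oracle", {
  # identity weights reproduce the input capsule
  W <- array(0, c(2, 2, 3, 2))
  for (i in 1:3) for (j in 1:2) W[, , i, j] <- diag(2)
  U <- matrix(rnorm(6), 2, 3)
  u_hat <- predict_vectors(W, U)
  for (j in 1:2) expect_equal(u_hat[, , j], U)

  # scalar matrix doubles it
  W2 <- W * 2
  expect_equal(predict_vectors(W2, matrix(c(1, -1), 2, 1)[, rep(1, 3)])[, 1, 1],
               c(2, -2))

  set.seed(2)
  for (rep in 1:10) {
    d_in <- sample(2:8, 1); d_out <- sample(2:16, 1)
    n_in <- sample(1:4, 1); K <- sample(1:3, 1)
    W <- array(rnorm(d_out * d_in * n_in * K), c(d_out, d_in, n_in, K))
    U <- matrix(rnorm(d_in * n_in), d_in, n_in)
    expect_equal(predict_vectors(W, U), predict_vectors_oracle(W, U),
                 tolerance = 1e-12)
  }
  expect_error(predict_vectors(W, U[, c(1, 1), drop = FALSE][-1, , drop = FALSE]),
               "mismatch")
})

test_that("dynamic routing matches a plain-loop oracle and normalizes couplings", {
  set.seed(3)
  for (rep in 1:20) {
    d_out <- sample(2:4, 1); n_in <- sample(1:4, 1); K <- sample(1:3, 1)
    u_hat <- array(rnorm(d_out * n_in * K), c(d_out, n_in, K))
    for (iters in 1:3) {
      got <- dynamic_routing(u_hat, iters)
      ref <- routing_oracle(u_hat, iters)
      expect_equal(got$C, ref$C, tolerance = 1e-10)
      expect_equal(got$V, ref$V, tolerance = 1e-10)
      expect_equal(rowSums(got$C), rep(1, n_in), tolerance = 1e-10)
      expect_true(all(sqrt(colSums(got$V^2)) < 1))
    }
  }
  expect_error(dynamic_routing(array(1, c(2, 2, 2)), 0), "at least 1")
})

test_that("routing degenerate and closed-form cases behave as derived", {
  set.seed(4)
  # single parent: softmax over one logit is identically 1
  u_hat <- array(rnorm(3 * 4 * 1), c(3, 4, 1))
  for (iters in c(1, 3, 5)) {
    expect_equal(dynamic_routing(u_hat, iters)$C, matrix(1, 4, 1))
  }
  # one iteration: uniform couplings, S is the uniform-weighted sum
  u_hat <- array(rnorm(3 * 4 * 2), c(3, 4, 2))
  got <- dynamic_routing(u_hat, 1)
  expect_equal(got$C, matrix(0.5, 4, 2))
  for (j in 1:2) {
    expect_equal(got$S[, j], rowSums(u_hat[, , j]) * 0.5, tolerance = 1e-12)
    expect_equal(got$V[, j], squash_oracle(got$S[, j]), tolerance = 1e-12)
  }
})

test_that("agreement grows couplings toward the consensus parent", {
  # all input capsules predict the same vector for parent 1 and
  # scattered vectors for parent 2: C(:, 1) must rise monotonically
  set.seed(5)
  n_in <- 4
  u_hat <- array(0, c(3, n_in, 2))
  for (i in seq_len(n_in)) {
    u_hat[, i, 1] <- c(2, 0, 0)
    u_hat[, i, 2] <- rnorm(3, sd = 0.3)
  }
  c1 <- sapply(1:3, function(it) mean(dynamic_routing(u_hat, it)$C[, 1]))
  expect_true(all(diff(c1) > 0))
  expect_gt(c1[3], 0.5)
})
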