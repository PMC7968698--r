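# finite-difference verification of the layer gradients: the engine is
# hand-written, so every backward pass is checked against numerics

num_grad_check <- function(layers, x, y, n_per_param = 5, eps = 1e-5) {
  lossfun <- function(ll, xx = x) {
    fw <- trapnet:::stack_forward(ll, xx, TRUE)
    trapnet:::cross_entropy_loss(fw$out, y)$loss
  }
  fw <- trapnet:::stack_forward(layers, x, TRUE)
  ce <- trapnet:::cross_entropy_loss(fw$out, y)
  bw <- trapnet:::stack_backward(fw$layers, fw$caches, ce$grad)
  maxrel <- 0
  for (li in seq_along(layers)) {
    for (nm in names(bw$grads[[li]])) {
      g <- bw$grads[[li]][[nm]]
      for (pi in sample(length(g), min(n_per_param, length(g)))) {
        l2 <- fw$layers
        l2[[li]][[nm]][pi] <- l2[[li]][[nm]][pi] + eps
        lp <- lossfun(l2)
        l2[[li]][[nm]][pi] <- l2[[li]][[nm]][pi] - 2 * eps
        lm <- lossfun(l2)
        num <- (lp - lm) / (2 * eps)
        maxrel <- max(maxrel, abs(num - g[pi]) / max(1e-4, abs(num) + abs(g[pi])))
      }
    }
  }
  # input gradient too
  for (pi in sample(length(x), 8)) {
    x2 <- x
    x2[pi] <- x2[pi] + eps
    lp <- lossfun(fw$layers, x2)
    x2[pi] <- x2[pi] - 2 * eps
    lm <- lossfun(fw$layers, x2)
    num <- (lp - lm) / (2 * eps)
    maxrel <- max(maxrel, abs(num - bw$gx[pi]) / max(1e-4, abs(num) + abs(bw$gx[pi])))
  }
  maxrel
}

test_that("conv/bn/pool/dense gradients match finite differences", {
  set.seed(1)
  layers <- list(trapnet:::nn_conv(3, 1, 3, stride = 1, pad = 1),
                 trapnet:::nn_bn(3), trapnet:::nn_relu(),
                 trapnet:::nn_pool(), trapnet:::nn_flatten(),
                 trapnet:::nn_dense(4 * 4 * 3, 4))
  x <- array(rnorm(8 * 8 * 5), c(8, 8, 5, 1))
  expect_lt(num_grad_check(layers, x, c(1, 2, 3, 4, 1)), 1e-5)
})

test_that("strided and valid convolutions are consistent with numerics", {
  set.seed(2)
  layers <- list(trapnet:::nn_conv(3, 1, 2, stride = 2, pad = 1),
                 trapnet:::nn_relu(),
                 trapnet:::nn_conv(3, 2, 3, stride = 1, pad = 0),
                 trapnet:::nn_flatten(),
                 trapnet:::nn_dense(2 * 2 * 3, 3))
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4, 1))
  expect_lt(num_grad_check(layers, x, c(3, 1, 2, 3)), 1e-5)
})

test_that("capsule network gradients are exact under fixed couplings", {
  set.seed(3)
  spec <- build_capsnet(conv1_filters = 2, primary_types = 2,
                        decoder_units = c(6, 8))
  model <- trapnet:::init_model(spec)
  x <- array(runif(60 * 60 * 2), c(60, 60, 2, 1))
  y <- c(2, 5)
  targets <- t(matrix(x, 3600, 2))
  # one routing iteration: couplings are constant, so the stop-gradient
  # backward pass must agree with numerics everywhere
  lossfun <- function(m) {
    fwd <- trapnet:::capsnet_forward(m, spec, x, TRUE, 1, y = y, targets = targets)
    trapnet:::margin_loss(fwd$lens, y)$loss +
      0.0005 * sum((fwd$dec$out - targets)^2) / 2
  }
  fwd <- trapnet:::capsnet_forward(model, spec, x, TRUE, 1, y = y, targets = targets)
  bw <- trapnet:::capsnet_backward(model, spec, fwd, y, targets)
  eps <- 1e-5
  check <- function(get, set, g, k = 6) {
    maxrel <- 0
    for (pi in sample(length(g), k)) {
      m2 <- set(model, pi, eps); lp <- lossfun(m2)
      m2 <- set(model, pi, -eps); lm <- lossfun(m2)
      num <- (lp - lm) / (2 * eps)
      maxrel <- max(maxrel, abs(num - g[pi]) / max(1e-4, abs(num) + abs(g[pi])))
    }
    maxrel
  }
  expect_lt(check(NULL, function(m, pi, e) {
    m$caps$W[pi] <- m$caps$W[pi] + e; m
  }, bw$grad_caps$W, 8), 1e-4)
  expect_lt(check(NULL, function(m, pi, e) {
    m$conv_layers[[1]]$W[pi] <- m$conv_layers[[1]]$W[pi] + e; m
  }, bw$grads_conv[[1]]$W), 1e-4)
  expect_lt(check(NULL, function(m, pi, e) {
    m$conv_layers[[3]]$W[pi] <- m$conv_layers[[3]]$W[pi] + e; m
  }, bw$grads_conv[[3]]$W), 1e-4)
  expect_lt(check(NULL, function(m, pi, e) {
    m$decoder[[1]]$W[pi] <- m$decoder[[1]]$W[pi] + e; m
  }, bw$grads_dec[[1]]$W), 1e-4)
})

test_that("margin loss matches its closed form on a worked example", {
  lens <- matrix(c(0.95, 0.05, 0.2, 0.05, 0.05), 5, 1)
  ml <- trapnet:::margin_loss(lens, 1L)
  # correct class above m+ = 0.9 contributes 0; others below m- except 0.2
  expect_equal(ml$loss, 0.5 * (0.2 - 0.1)^2, tolerance = 1e-12)
  lens2 <- matrix(c(0.5, rep(0, 4)), 5, 1)
  ml2 <- trapnet:::margin_loss(lens2, 1L)
  expect_equal(ml2$loss, (0.9 - 0.5)^2, tolerance = 1e-12)
})
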