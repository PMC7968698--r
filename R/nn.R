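# Minimal feed-forward network engine: plain R, BLAS-backed.
#
# Batch tensors are arrays dim c(H, W, N, C) — channels last, so the
# (pixels*batch) x channels matrix views needed by convolution and batch
# norm are plain dim changes with no data movement. Dense activations
# are matrices dim c(N, features). Convolution is im2col + GEMM; every
# layer has an explicit backward pass (verified by finite-difference
# tests). No external deep-learning framework exists in the target
# environment, so this engine is part of the package.

# ---- im2col -------------------------------------------------------------

# x: (H, W, N, C) -> matrix (k*k*C) x (OH*OW*N); columns ordered
# (oh fastest, ow, n); rows ordered (dh fastest, dw, c). Compiled kernel.
im2col <- function(x, k, stride) {
  cpp_im2col(x, dim(x), as.integer(k), as.integer(stride))
}

zero_pad <- function(x, p) {
  if (p == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3], d[4]))
  out[(p + 1):(p + d[1]), (p + 1):(p + d[2]), , ] <- x
  out
}

conv_out_side <- function(n, k, stride, pad) (n + 2 * pad - k) %/% stride + 1L

# ---- layer constructors -------------------------------------------------

nn_conv <- function(k, in_ch, out_ch, stride = 1L, pad = 0L) {
  list(kind = "conv", k = as.integer(k), in_ch = in_ch, out_ch = out_ch,
       stride = as.integer(stride), pad = as.integer(pad),
       W = matrix(stats::rnorm(k * k * in_ch * out_ch,
                               sd = sqrt(2 / (k * k * in_ch))),
                  k * k * in_ch, out_ch),
       b = numeric(out_ch))
}

nn_bn <- function(ch, eps = 1e-5, momentum = 0.9) {
  list(kind = "bn", ch = ch, eps = eps, momentum = momentum,
       gamma = rep(1, ch), beta = numeric(ch),
       run_mean = numeric(ch), run_var = rep(1, ch))
}

nn_relu <- function() list(kind = "relu")
nn_pool <- function() list(kind = "pool")             # 2x2 max pool, stride 2
nn_dropout <- function(rate) list(kind = "dropout", rate = rate)
nn_flatten <- function() list(kind = "flatten")
nn_sigmoid <- function() list(kind = "sigmoid")

nn_dense <- function(d_in, d_out) {
  list(kind = "dense", d_in = d_in, d_out = d_out,
       W = matrix(stats::rnorm(d_in * d_out, sd = sqrt(2 / d_in)), d_in, d_out),
       b = numeric(d_out))
}

# ---- forward / backward per layer --------------------------------------

layer_forward <- function(layer, x, train) {
  switch(layer$kind,
    conv = {
      xp <- zero_pad(x, layer$pad)
      OH <- conv_out_side(dim(x)[1], layer$k, layer$stride, layer$pad)
      OW <- conv_out_side(dim(x)[2], layer$k, layer$stride, layer$pad)
      N <- dim(x)[3]
      cols <- im2col(xp, layer$k, layer$stride)
      out_mat <- crossprod(cols, layer$W)            # (OH*OW*N) x out_ch
      out_mat <- out_mat + rep(layer$b, each = nrow(out_mat))
      out <- array(out_mat, c(OH, OW, N, layer$out_ch))
      list(out = out, cache = list(cols = cols, in_dim = dim(x), OH = OH, OW = OW))
    },
    bn = {
      d <- dim(x)
      m <- prod(d[-4])
      xm <- matrix(x, ncol = d[4])                   # (H*W*N) x C, no copy
      if (!isFALSE(train)) {
        mu <- colMeans(xm)
        va <- pmax(colMeans(xm^2) - mu^2, 0)
        layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
        layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * va
      } else {
        mu <- layer$run_mean
        va <- layer$run_var
      }
      invstd <- 1 / sqrt(va + layer$eps)
      xhat <- (xm - rep(mu, each = m)) * rep(invstd, each = m)
      out_m <- xhat * rep(layer$gamma, each = m) + rep(layer$beta, each = m)
      out <- array(out_m, d)
      list(out = out, cache = list(xhat = xhat, invstd = invstd, d = d, m = m,
                                   mu = mu, va = va),
           layer = layer)
    },
    relu = list(out = pmax(x, 0), cache = list(pos = x > 0)),
    sigmoid = {
      s <- 1 / (1 + exp(-x))
      list(out = s, cache = list(s = s))
    },
    pool = {
      d <- dim(x)
      Hh <- d[1] %/% 2L; Wh <- d[2] %/% 2L
      x <- x[seq_len(2 * Hh), seq_len(2 * Wh), , , drop = FALSE]
      s11 <- x[seq(1, 2 * Hh, 2), seq(1, 2 * Wh, 2), , , drop = FALSE]
      s21 <- x[seq(2, 2 * Hh, 2), seq(1, 2 * Wh, 2), , , drop = FALSE]
      s12 <- x[seq(1, 2 * Hh, 2), seq(2, 2 * Wh, 2), , , drop = FALSE]
      s22 <- x[seq(2, 2 * Hh, 2), seq(2, 2 * Wh, 2), , , drop = FALSE]
      out <- pmax(s11, s21, s12, s22)
      list(out = out, cache = list(s = list(s11, s21, s12, s22), out = out,
                                   in_dim = d, Hh = Hh, Wh = Wh))
    },
    dropout = {
      if (isTRUE(train) && layer$rate > 0) {
        mask <- array(stats::runif(length(x)) >= layer$rate, dim(x)) / (1 - layer$rate)
        list(out = x * mask, cache = list(mask = mask))
      } else {
        list(out = x, cache = list(mask = NULL))
      }
    },
    flatten = {
      d <- dim(x)                                    # (H, W, N, C)
      xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = d[3])
      list(out = t(xm), cache = list(d = d))
    },
    dense = {
      list(out = x %*% layer$W + rep(layer$b, each = nrow(x)),
           cache = list(x = x))
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

layer_backward <- function(layer, cache, g) {
  switch(layer$kind,
    conv = {
      OH <- cache$OH; OW <- cache$OW
      din <- cache$in_dim                            # (H, W, N, C)
      N <- din[3]; C <- din[4]
      g_mat <- matrix(g, ncol = layer$out_ch)
      gW <- cache$cols %*% g_mat
      gb <- colSums(g_mat)
      k <- layer$k; s <- layer$stride; p <- layer$pad
      gcols <- tcrossprod(layer$W, g_mat)            # (k*k*C) x (OH*OW*N)
      gx <- cpp_col2im(gcols, c(din[1] + 2L * p, din[2] + 2L * p, N, C),
                       k, s)
      if (p > 0) {
        gx <- gx[(p + 1):(p + din[1]), (p + 1):(p + din[2]), , , drop = FALSE]
      }
      list(gx = gx, grads = list(W = gW, b = gb))
    },
    bn = {
      d <- cache$d; m <- cache$m
      gm <- matrix(g, ncol = d[4])
      ggamma <- colSums(gm * cache$xhat)
      gbeta <- colSums(gm)
      gxhat <- gm * rep(layer$gamma, each = m)
      sx <- colSums(gxhat)
      sxx <- colSums(gxhat * cache$xhat)
      gxm <- (gxhat - rep(sx / m, each = m) -
              cache$xhat * rep(sxx / m, each = m)) * rep(cache$invstd, each = m)
      gx <- array(gxm, d)
      list(gx = gx, grads = list(gamma = ggamma, beta = gbeta))
    },
    relu = list(gx = g * cache$pos, grads = NULL),
    sigmoid = list(gx = g * cache$s * (1 - cache$s), grads = NULL),
    pool = {
      d <- cache$in_dim; Hh <- cache$Hh; Wh <- cache$Wh
      gx <- array(0, d)
      taken <- array(FALSE, dim(cache$out))
      ri <- list(seq(1, 2 * Hh, 2), seq(2, 2 * Hh, 2))
      ci <- list(seq(1, 2 * Wh, 2), seq(2, 2 * Wh, 2))
      srcs <- list(c(1, 1), c(2, 1), c(1, 2), c(2, 2))
      for (q in seq_along(srcs)) {
        sq <- cache$s[[q]]
        hit <- (sq == cache$out) & !taken
        taken <- taken | hit
        rr <- ri[[srcs[[q]][1]]]; cc <- ci[[srcs[[q]][2]]]
        gx[rr, cc, , ] <- gx[rr, cc, , , drop = FALSE] + g * hit
      }
      list(gx = gx, grads = NULL)
    },
    dropout = {
      if (is.null(cache$mask)) list(gx = g, grads = NULL)
      else list(gx = g * cache$mask, grads = NULL)
    },
    flatten = {
      d <- cache$d
      gx <- aperm(array(t(g), c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
      list(gx = gx, grads = NULL)
    },
    dense = {
      list(gx = tcrossprod(g, layer$W),
           grads = list(W = crossprod(cache$x, g), b = colSums(g)))
    },
    stop("unknown layer kind: ", layer$kind)
  )
}

# Forward a whole stack; returns activations + caches. BN layers mutate
# running stats during training, so the (possibly updated) layers are
# returned too.
stack_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    f <- layer_forward(layers[[i]], x, train)
    x <- f$out
    caches[[i]] <- f$cache
    if (!is.null(f$layer)) layers[[i]] <- f$layer
  }
  list(out = x, caches = caches, layers = layers)
}

stack_backward <- function(layers, caches, g) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    b <- layer_backward(layers[[i]], caches[[i]], g)
    g <- b$gx
    grads[i] <- list(b$grads)   # keep NULL slots for parameter-free layers
  }
  list(gx = g, grads = grads)
}

stack_param_count <- function(layers) {
  sum(vapply(layers, function(l) {
    sum(vapply(intersect(names(l), c("W", "b", "gamma", "beta")),
               function(nm) length(l[[nm]]), numeric(1)))
  }, numeric(1)))
}

# Recompute BN running statistics under the current weights ("precise
# BN"): forward up to max_n training images in batch-stats mode (dropout
# off) and set each BN layer's running mean/var to the average of its
# batch statistics. With few optimizer steps the momentum-tracked stats
# lag the weights badly, which wrecks inference through deep BN stacks.
bn_refresh <- function(layers, x_all, batch_size = 64L, max_n = 192L) {
  n <- dim(x_all)[3]
  take <- unique(round(seq(1, n, length.out = min(n, max_n))))
  sums <- vector("list", length(layers))
  counts <- 0L
  for (start in seq(1, length(take), by = batch_size)) {
    idx <- take[start:min(start + batch_size - 1, length(take))]
    x <- x_all[, , idx, , drop = FALSE]
    for (i in seq_along(layers)) {
      f <- layer_forward(layers[[i]], x, train = "stats")
      x <- f$out
      if (layers[[i]]$kind == "bn") {
        if (is.null(sums[[i]])) sums[[i]] <- list(mu = 0, va = 0)
        sums[[i]]$mu <- sums[[i]]$mu + f$cache$mu
        sums[[i]]$va <- sums[[i]]$va + f$cache$va
      }
    }
    counts <- counts + 1L
  }
  for (i in seq_along(layers)) {
    if (!is.null(sums[[i]])) {
      layers[[i]]$run_mean <- sums[[i]]$mu / counts
      layers[[i]]$run_var <- sums[[i]]$va / counts
    }
  }
  layers
}

# ---- losses -------------------------------------------------------------

softmax_mat <- function(z) {
  e <- exp(z - apply(z, 1, max))
  e / rowSums(e)
}

# logits (N x K), y integer class index; returns loss + gradient d logits
cross_entropy_loss <- function(logits, y) {
  p <- softmax_mat(logits)
  n <- nrow(logits)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(n), y)] + eps))
  g <- p
  g[cbind(seq_len(n), y)] <- g[cbind(seq_len(n), y)] - 1
  list(loss = loss, grad = g / n, p = p)
}

# capsule margin loss on class-capsule lengths (K x N), y integer index
margin_loss <- function(lens, y, m_pos = 0.9, m_neg = 0.1, lambda = 0.5) {
  K <- nrow(lens); n <- ncol(lens)
  T_ <- matrix(0, K, n)
  T_[cbind(y, seq_len(n))] <- 1
  a <- pmax(0, m_pos - lens)
  b <- pmax(0, lens - m_neg)
  loss <- sum(T_ * a^2 + lambda * (1 - T_) * b^2) / n
  grad <- (-2 * T_ * a + 2 * lambda * (1 - T_) * b) / n
  list(loss = loss, grad = grad)
}

# ---- Adam ---------------------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(l) {
    nms <- intersect(names(l), c("W", "b", "gamma", "beta"))
    if (!length(nms)) return(NULL)
    st <- list()
    for (nm in nms) st[[nm]] <- list(m = l[[nm]] * 0, v = l[[nm]] * 0)
    st
  })
}

adam_step <- function(layers, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (i in seq_along(layers)) {
    gl <- grads[[i]]
    if (is.null(gl)) next
    for (nm in names(gl)) {
      g <- gl[[nm]]
      s <- state[[i]][[nm]]
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g * g
      mhat <- s$m / (1 - beta1^t)
      vhat <- s$v / (1 - beta2^t)
      layers[[i]][[nm]] <- layers[[i]][[nm]] - lr * mhat / (sqrt(vhat) + eps)
      state[[i]][[nm]] <- s
    }
  }
  list(layers = layers, state = state)
}

# batched squash over columns of a matrix, plus its backward
squash_cols <- function(S, eps = 1e-12) {
  n2 <- colSums(S * S)
  sc <- n2 / (1 + n2) / sqrt(n2 + eps)
  sweep(S, 2, sc, `*`)
}

squash_cols_backward <- function(S, G, eps = 1e-12) {
  n2 <- colSums(S * S)
  n <- sqrt(n2 + eps)
  fn <- n2 / (1 + n2)
  fp <- 2 * n / (1 + n2)^2
  dot <- colSums(S * G)
  sweep(G, 2, fn / n, `*`) +
    sweep(S, 2, (fp - fn / n) * dot / (n2 + eps), `*`)
}
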