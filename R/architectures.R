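#' Model specifications: CNN-2, CNN-13, CapsNet
#'
#' Three classifier architectures over 60x60 single-channel trap images,
#' all emitting a 5-category probability vector:
#'
#' * `build_cnn2()` — the baseline 2-layer CNN: two 3x3 convolutions
#'   (strides 1 and 2, batch normalization and ReLU on both), 2x2
#'   max-pooling, 25% dropout on the second layer, a 128-unit dense layer
#'   and a 5-way softmax head.
#' * `build_cnn13()` — a 13-convolution network in homogeneous groups
#'   (SimpleNet-style), 3x3 kernels, 2x2 pooling between groups, batch
#'   normalization and 25% dropout on every layer, single dense softmax
#'   head.
#' * `build_capsnet()` — the baseline capsule network: a 9x9 convolution
#'   (stride 1, valid) giving 52x52 feature maps, a 9x9 stride-2 primary
#'   capsule convolution giving a 22x22 spatial grid reshaped to
#'   22x22x`primary_types` capsules of dimension 8, dynamic routing to 5
#'   class capsules of dimension 16, and a dense decoder that
#'   reconstructs the input from the correct class capsule. Class scores
#'   are the capsule output lengths normalized to sum to 1.
#'
#' `width_scale` multiplies all channel counts; training at desk scale on
#' one CPU uses a reduced scale while the defaults state the reference
#' architecture (the spatial shape chain is unaffected by widths).
#'
#' @param filters,widths convolution channel counts.
#' @param dense_units hidden dense width of CNN-2.
#' @param width_scale multiplier applied to all channel counts (min 1).
#' @param dropout dropout rate (0.25 as specified).
#' @param conv1_filters CapsNet first-convolution channels (256 in the
#'   reference baseline).
#' @param primary_types number of primary-capsule types (32 in the
#'   reference; the primary convolution emits `8 * primary_types`
#'   channels).
#' @param decoder_units hidden widths of the reconstruction decoder.
#' @return A list of class `model_spec`.
#' @export
build_cnn2 <- function(filters = c(16, 32), dense_units = 128,
                       width_scale = 1, dropout = 0.25) {
  f <- pmax(1L, round(filters * width_scale))
  structure(list(architecture_id = "cnn2", filters = f,
                 dense_units = dense_units, dropout = dropout,
                 n_class = 5L),
            class = "model_spec")
}

#' @rdname build_cnn2
#' @export
build_cnn13 <- function(widths = c(64, 96, 96, 96, 128, 128, 128,
                                   192, 192, 192, 256, 256, 128),
                        width_scale = 1, dropout = 0.25) {
  stopifnot(length(widths) == 13)
  w <- pmax(1L, round(widths * width_scale))
  structure(list(architecture_id = "cnn13", widths = w, dropout = dropout,
                 pool_after = c(2L, 5L, 8L, 11L), n_class = 5L),
            class = "model_spec")
}

#' @rdname build_cnn2
#' @export
build_capsnet <- function(conv1_filters = 256, primary_types = 32,
                          width_scale = 1, decoder_units = c(256, 512)) {
  f1 <- max(1L, round(conv1_filters * width_scale))
  pt <- max(1L, round(primary_types * width_scale))
  side1 <- conv_out_side(60L, 9L, 1L, 0L)          # 52
  side2 <- conv_out_side(side1, 9L, 2L, 0L)        # 22
  stopifnot(side1 == 52L, side2 == 22L)
  structure(list(architecture_id = "capsnet", conv1_filters = f1,
                 primary_types = pt, primary_dim = 8L, class_dim = 16L,
                 primary_grid = side2, n_primary = side2 * side2 * pt,
                 decoder_units = decoder_units, n_class = 5L),
            class = "model_spec")
}

# ---- parameter initialization ------------------------------------------

init_model <- function(spec) {
  switch(spec$architecture_id,
    cnn2 = {
      f <- spec$filters
      list(layers = list(
        nn_conv(3, 1, f[1], stride = 1, pad = 1), nn_bn(f[1]), nn_relu(),
        nn_conv(3, f[1], f[2], stride = 2, pad = 1), nn_bn(f[2]), nn_relu(),
        nn_pool(), nn_dropout(spec$dropout), nn_flatten(),
        nn_dense(15 * 15 * f[2], spec$dense_units), nn_relu(),
        nn_dense(spec$dense_units, spec$n_class)))
    },
    cnn13 = {
      w <- spec$widths
      layers <- list()
      in_ch <- 1
      side <- 60
      for (i in 1:13) {
        layers <- c(layers, list(
          nn_conv(3, in_ch, w[i], stride = 1, pad = 1), nn_bn(w[i]),
          nn_relu(), nn_dropout(spec$dropout)))
        in_ch <- w[i]
        if (i %in% spec$pool_after) {
          layers <- c(layers, list(nn_pool()))
          side <- side %/% 2
        }
      }
      layers <- c(layers, list(nn_flatten(),
                               nn_dense(side * side * w[13], spec$n_class)))
      list(layers = layers)
    },
    capsnet = {
      pd <- spec$primary_dim
      conv_layers <- list(
        nn_conv(9, 1, spec$conv1_filters, stride = 1, pad = 0), nn_relu(),
        nn_conv(9, spec$conv1_filters, pd * spec$primary_types,
                stride = 2, pad = 0))
      W_caps <- array(stats::rnorm(spec$class_dim * pd * spec$n_primary * spec$n_class,
                                   sd = 0.1),
                      c(spec$class_dim, pd, spec$n_primary, spec$n_class))
      du <- spec$decoder_units
      decoder <- list(
        nn_dense(spec$n_class * spec$class_dim, du[1]), nn_relu(),
        nn_dense(du[1], du[2]), nn_relu(),
        nn_dense(du[2], 60 * 60), nn_sigmoid())
      list(conv_layers = conv_layers,
           caps = list(kind = "caps", W = W_caps),
           decoder = decoder)
    },
    stop("unknown architecture: ", spec$architecture_id)
  )
}

#' Number of learnable parameters of a model spec
#' @param spec a `model_spec`.
#' @export
param_count <- function(spec) {
  m <- init_model(spec)
  if (spec$architecture_id == "capsnet") {
    stack_param_count(m$conv_layers) + length(m$caps$W) +
      stack_param_count(m$decoder)
  } else {
    stack_param_count(m$layers)
  }
}

# ---- CapsNet forward / backward ----------------------------------------

# y: primary conv output (G, G, N, pd*T) -> pre-squash capsules (pd, n_caps, N)
caps_reshape <- function(y, pd, types) {
  d <- dim(y)
  G2 <- d[1] * d[2]; N <- d[3]
  m <- aperm(array(y, c(G2, N, pd, types)), c(3, 1, 4, 2))
  array(m, c(pd, G2 * types, N))
}

caps_reshape_back <- function(ds, G, pd, types, N) {
  m <- array(ds, c(pd, G * G, types, N))
  array(aperm(m, c(2, 4, 1, 3)), c(G, G, N, pd * types))
}

# batched prediction vectors: u (pd, n_caps, N) -> list of 5 arrays
# (class_dim, n_caps, N)
caps_predict_all <- function(W, u) {
  dd <- dim(W)                         # (class_dim, pd, n_caps, n_class)
  cd <- dd[1]; pd <- dd[2]; n_caps <- dd[3]; K <- dd[4]
  N <- dim(u)[3]
  u_hat <- vector("list", K)
  for (j in seq_len(K)) {
    acc <- array(0, c(cd, n_caps, N))
    for (k in seq_len(pd)) {
      acc <- acc + as.vector(W[, k, , j]) * rep(u[k, , ], each = cd)
    }
    u_hat[[j]] <- acc
  }
  u_hat
}

# batched dynamic routing; C is treated as constant in the backward pass
caps_route <- function(u_hat, iterations) {
  K <- length(u_hat)
  cd <- dim(u_hat[[1]])[1]; n_caps <- dim(u_hat[[1]])[2]; N <- dim(u_hat[[1]])[3]
  B <- array(0, c(n_caps, K, N))
  C <- S <- V <- NULL
  for (it in seq_len(iterations)) {
    amax <- B[, 1, ]
    for (j in 2:K) amax <- pmax(amax, B[, j, ])
    E <- array(0, c(n_caps, K, N))
    for (j in seq_len(K)) E[, j, ] <- exp(B[, j, ] - amax)
    den <- E[, 1, ]
    for (j in 2:K) den <- den + E[, j, ]
    C <- E
    for (j in seq_len(K)) C[, j, ] <- E[, j, ] / den
    S <- array(0, c(cd, K, N))
    for (j in seq_len(K)) {
      M <- u_hat[[j]] * rep(C[, j, ], each = cd)
      S[, j, ] <- colSums(aperm(M, c(2, 1, 3)))
    }
    V <- array(squash_cols(matrix(S, cd, K * N)), c(cd, K, N))
    if (it < iterations) {
      for (j in seq_len(K)) {
        Vexp <- aperm(array(V[, j, ], c(cd, N, n_caps)), c(1, 3, 2))
        B[, j, ] <- B[, j, ] + colSums(u_hat[[j]] * Vexp)
      }
    }
  }
  list(C = C, S = S, V = V)
}

capsnet_forward <- function(model, spec, x, train, routing_iterations,
                            y = NULL, targets = NULL) {
  fw <- stack_forward(model$conv_layers, x, train)
  y_conv <- fw$out
  s_prim <- caps_reshape(y_conv, spec$primary_dim, spec$primary_types)
  n_caps <- dim(s_prim)[2]; N <- dim(s_prim)[3]
  u <- array(squash_cols(matrix(s_prim, spec$primary_dim, n_caps * N)),
             c(spec$primary_dim, n_caps, N))
  u_hat <- caps_predict_all(model$caps$W, u)
  rt <- caps_route(u_hat, routing_iterations)
  lens <- matrix(sqrt(colSums(matrix(rt$V^2, spec$class_dim, spec$n_class * N))),
                 spec$n_class, N)
  out <- list(conv = fw, s_prim = s_prim, u = u, u_hat = u_hat,
              route = rt, lens = lens, N = N, n_caps = n_caps)
  if (!is.null(y)) {
    # decoder on the true class capsule (training reconstruction target)
    D_in <- matrix(0, N, spec$n_class * spec$class_dim)
    for (n in seq_len(N)) {
      rows <- (y[n] - 1) * spec$class_dim + seq_len(spec$class_dim)
      D_in[n, rows] <- rt$V[, y[n], n]
    }
    dec <- stack_forward(model$decoder, D_in, train)
    out$D_in <- D_in
    out$dec <- dec
  }
  out
}

# returns gradients aligned with (conv_layers, caps, decoder) plus loss parts
capsnet_backward <- function(model, spec, fwd, y, targets,
                             recon_weight = 0.0005) {
  cd <- spec$class_dim; K <- spec$n_class
  N <- fwd$N; n_caps <- fwd$n_caps; pd <- spec$primary_dim
  ml <- margin_loss(fwd$lens, y)
  # margin gradient through the length
  dV <- array(0, c(cd, K, N))
  lens_safe <- pmax(fwd$lens, 1e-12)
  for (j in seq_len(K)) {
    dV[, j, ] <- fwd$route$V[, j, ] * rep(ml$grad[j, ] / lens_safe[j, ], each = cd)
  }
  # decoder reconstruction gradient
  recon <- fwd$dec$out
  rdiff <- recon - targets
  loss_rec <- recon_weight * sum(rdiff^2) / N
  bw_dec <- stack_backward(model$decoder, fwd$dec$caches,
                           recon_weight * 2 * rdiff / N)
  gD <- bw_dec$gx
  for (n in seq_len(N)) {
    rows <- (y[n] - 1) * cd + seq_len(cd)
    dV[, y[n], n] <- dV[, y[n], n] + gD[n, rows]
  }
  # squash backward at the class capsules
  dS <- array(squash_cols_backward(matrix(fwd$route$S, cd, K * N),
                                   matrix(dV, cd, K * N)),
              c(cd, K, N))
  # routing backward with couplings fixed
  gW <- array(0, dim(model$caps$W))
  du <- array(0, c(pd, n_caps, N))
  for (j in seq_len(K)) {
    dSexp <- aperm(array(dS[, j, ], c(cd, N, n_caps)), c(1, 3, 2))
    du_hat_j <- dSexp * rep(fwd$route$C[, j, ], each = cd)
    for (k in seq_len(pd)) {
      T_ <- du_hat_j * rep(fwd$u[k, , ], each = cd)
      gW[, k, , j] <- matrix(rowSums(matrix(T_, cd * n_caps, N)), cd, n_caps)
      du[k, , ] <- du[k, , ] + colSums(du_hat_j * as.vector(model$caps$W[, k, , j]))
    }
  }
  ds_prim <- array(squash_cols_backward(matrix(fwd$s_prim, pd, n_caps * N),
                                        matrix(du, pd, n_caps * N)),
                   c(pd, n_caps, N))
  g_conv_out <- caps_reshape_back(ds_prim, spec$primary_grid, pd,
                                  spec$primary_types, N)
  bw_conv <- stack_backward(model$conv_layers, fwd$conv$caches, g_conv_out)
  list(loss = ml$loss + loss_rec, margin_loss = ml$loss, recon_loss = loss_rec,
       grads_conv = bw_conv$grads, grad_caps = list(W = gW),
       grads_dec = bw_dec$grads)
}

capsnet_probs <- function(lens) {
  tot <- pmax(colSums(lens), 1e-12)
  t(sweep(lens, 2, tot, `/`))
}

# ---- hyper-parameters ---------------------------------------------------

#' Training hyper-parameters
#'
#' The six searched hyper-parameters (routing iterations — capsule network
#' only —, learning rate, batch size, whether to add noise to training
#' images, epochs, whether to augment) plus the seed and the augmentation
#' configuration used when `augmentation = TRUE`. The noise flag is
#' independent of the augmentation pipeline's own noise.
#'
#' @param routing_iterations routing iterations (capsnet only), >= 1.
#' @param learning_rate Adam learning rate, > 0.
#' @param batch_size mini-batch size, > 0.
#' @param add_noise add Gaussian noise (sd `noise_sigma`) to each training
#'   batch.
#' @param epochs training epochs.
#' @param augmentation augment the training split before training.
#' @param aug_cfg an [augmentation_config()]; the default uses a modest
#'   multiplier of 2 to keep CPU runs tractable (the full-scale setting
#'   would be 32).
#' @param noise_sigma sd of the `add_noise` perturbation.
#' @param seed integer seed controlling initialization, shuffling,
#'   dropout and noise.
#' @return A list of class `hyper_params`.
#' @export
hyper_params <- function(routing_iterations = 3L, learning_rate = 1e-3,
                         batch_size = 32L, add_noise = FALSE, epochs = 5L,
                         augmentation = FALSE,
                         aug_cfg = augmentation_config(multiplier = 2L),
                         noise_sigma = 0.02, seed = 1L) {
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (batch_size < 1) stop("batch_size must be positive")
  if (routing_iterations < 1) stop("routing_iterations must be >= 1")
  if (epochs < 1) stop("epochs must be >= 1")
  structure(list(routing_iterations = as.integer(routing_iterations),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 add_noise = add_noise, epochs = as.integer(epochs),
                 augmentation = augmentation, aug_cfg = aug_cfg,
                 noise_sigma = noise_sigma, seed = as.integer(seed)),
            class = "hyper_params")
}

as_batch_array <- function(imgs) {
  d <- dim(imgs)                       # (H, W, N) -> (H, W, N, 1)
  array(imgs, c(d[1], d[2], d[3], 1))
}

# ---- training -----------------------------------------------------------

#' Train a classifier on a trap dataset
#'
#' Trains the given architecture with Adam on the dataset's training
#' split (optionally augmented) and records per-epoch history; validation
#' accuracy is computed on the untouched validation split after every
#' epoch, and the returned parameters are those of the best-validation
#' epoch (its accuracy becomes the model's `validation_accuracy`, the
#' ensemble weighting signal). With a fixed seed the run is reproducible.
#'
#' @param spec a `model_spec` from [build_cnn2()], [build_cnn13()] or
#'   [build_capsnet()].
#' @param dataset a `trap_dataset` with nonempty train and val splits.
#' @param hp a [hyper_params()] object.
#' @param verbose print per-epoch progress.
#' @return A `trained_model`: list with `spec`, `model` (parameters),
#'   `history` (data frame epoch/loss/acc/val_acc), `validation_accuracy`,
#'   and the feature-normalization stats if used.
#' @export
train_model <- function(spec, dataset, hp = hyper_params(), verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"), inherits(dataset, "trap_dataset"),
            inherits(hp, "hyper_params"))
  train_ds <- dataset_subset(dataset, "train")
  val_ds <- dataset_subset(dataset, "val")
  if (dataset_size(train_ds) == 0) stop("empty training split")
  if (dataset_size(val_ds) == 0) stop("empty validation split")
  if (hp$augmentation) {
    train_ds <- augment_dataset(train_ds, hp$aug_cfg, seed = hp$seed + 1000L)
  }
  fstats <- NULL
  if (isTRUE(hp$aug_cfg$featurewise_center) ||
      isTRUE(hp$aug_cfg$featurewise_std_normalization)) {
    fstats <- fit_feature_stats(train_ds)
    if (!hp$aug_cfg$featurewise_std_normalization) fstats$sd[] <- 0
    train_ds$images <- apply_feature_norm(train_ds$images, fstats)
  }
  x_all <- as_batch_array(train_ds$images)
  y_all <- match(train_ds$labels, category5_levels())
  n <- length(y_all)
  caps <- spec$architecture_id == "capsnet"
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        acc = numeric(0), val_acc = numeric(0))
  model <- NULL
  best_val <- -Inf
  best_model <- NULL
  with_seed(hp$seed, {
    model <- init_model(spec)
    layers_flat <- if (caps) c(model$conv_layers, list(model$caps), model$decoder)
                   else model$layers
    opt <- adam_init(layers_flat)
    t_step <- 0L
    n_conv <- if (caps) length(model$conv_layers) else 0L
    n_dec <- if (caps) length(model$decoder) else 0L
    for (epoch in seq_len(hp$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0; n_batches <- 0
      for (start in seq(1, n, by = hp$batch_size)) {
        idx <- ord[start:min(start + hp$batch_size - 1, n)]
        xb <- x_all[, , idx, , drop = FALSE]
        yb <- y_all[idx]
        if (hp$add_noise) {
          xb <- xb + array(stats::rnorm(length(xb), 0, hp$noise_sigma), dim(xb))
        }
        if (caps) {
          targets <- t(matrix(xb, 60 * 60, length(idx)))
          fwd <- capsnet_forward(model, spec, xb, TRUE, hp$routing_iterations,
                                 y = yb, targets = targets)
          model$conv_layers <- fwd$conv$layers
          model$decoder <- fwd$dec$layers
          bw <- capsnet_backward(model, spec, fwd, yb, targets)
          grads <- c(bw$grads_conv, list(bw$grad_caps), bw$grads_dec)
          layers_flat <- c(model$conv_layers, list(model$caps), model$decoder)
          t_step <- t_step + 1L
          st <- adam_step(layers_flat, grads, opt, hp$learning_rate, t_step)
          opt <- st$state
          model$conv_layers <- st$layers[seq_len(n_conv)]
          model$caps <- st$layers[[n_conv + 1L]]
          model$decoder <- st$layers[n_conv + 1L + seq_len(n_dec)]
          loss <- bw$loss
          pred <- apply(fwd$lens, 2, which.max)
        } else {
          fwd <- stack_forward(model$layers, xb, TRUE)
          model$layers <- fwd$layers
          ce <- cross_entropy_loss(fwd$out, yb)
          bw <- stack_backward(model$layers, fwd$caches, ce$grad)
          t_step <- t_step + 1L
          st <- adam_step(model$layers, bw$grads, opt, hp$learning_rate, t_step)
          model$layers <- st$layers
          opt <- st$state
          loss <- ce$loss
          pred <- max.col(ce$p, ties.method = "first")
        }
        ep_loss <- ep_loss + loss
        ep_correct <- ep_correct + sum(pred == yb)
        n_batches <- n_batches + 1
      }
      if (!caps) {
        # refresh BN running stats under the current weights before
        # evaluating; momentum tracking is too stale at this step count
        model$layers <- bn_refresh(model$layers, x_all, hp$batch_size)
      }
      tm <- structure(list(spec = spec, model = model, fstats = fstats,
                           routing_iterations = hp$routing_iterations,
                           batch_size = hp$batch_size),
                      class = "trained_model")
      val_p <- predict(tm, val_ds$images)
      val_acc <- mean(argmax_label(val_p) == val_ds$labels)
      history[nrow(history) + 1L, ] <- list(epoch, ep_loss / n_batches,
                                            ep_correct / n, val_acc)
      if (val_acc >= best_val) {       # keep the best-validation epoch
        best_val <- val_acc
        best_model <- model
      }
      if (verbose) {
        message(sprintf("[%s] epoch %d loss %.4f acc %.3f val_acc %.3f",
                        spec$architecture_id, epoch, ep_loss / n_batches,
                        ep_correct / n, val_acc))
      }
    }
  })
  structure(list(spec = spec, model = best_model, history = history,
                 validation_accuracy = best_val,
                 fstats = fstats, routing_iterations = hp$routing_iterations,
                 batch_size = hp$batch_size, hp = hp),
            class = "trained_model")
}

#' Predict category probabilities for trap images
#'
#' Runs the trained model in inference mode and returns one probability
#' vector per image over the 5 computed categories (rows sum to 1, batch
#' order preserved). For the capsule network the probabilities are the
#' class-capsule output lengths normalized by their sum.
#'
#' @param object a `trained_model`.
#' @param images a 60x60 matrix, a 60x60xN array, or a `trap_dataset`.
#' @param ... unused.
#' @return Numeric matrix N x 5 with `category5_levels()` column names.
#' @export
predict.trained_model <- function(object, images, ...) {
  if (inherits(images, "trap_dataset")) images <- images$images
  if (is.matrix(images)) images <- array(images, c(dim(images), 1))
  d <- dim(images)
  if (d[1] != 60 || d[2] != 60) {
    stop("images must be 60x60 (got ", d[1], "x", d[2], ")")
  }
  if (!is.null(object$fstats)) {
    images <- apply_feature_norm(images, object$fstats)
  }
  n <- d[3]
  spec <- object$spec
  bs <- if (spec$architecture_id == "capsnet") 32L else 64L
  out <- matrix(0, n, 5)
  for (start in seq(1, n, by = bs)) {
    idx <- start:min(start + bs - 1, n)
    xb <- as_batch_array(images[, , idx, drop = FALSE])
    if (spec$architecture_id == "capsnet") {
      fwd <- capsnet_forward(object$model, spec, xb, FALSE,
                             object$routing_iterations %||% 3L)
      out[idx, ] <- capsnet_probs(fwd$lens)
    } else {
      fw <- stack_forward(object$model$layers, xb, FALSE)
      out[idx, ] <- softmax_mat(fw$out)
    }
  }
  colnames(out) <- category5_levels()
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save / load a trained model checkpoint
#'
#' Single-file archive holding the spec, learned parameters, training
#' history and feature-normalization statistics. `save_training_log`
#' writes the per-epoch history as CSV (epoch, loss, acc, val_acc).
#'
#' @param model a `trained_model`.
#' @param path file path (`.rds` for checkpoints, `.csv` for logs).
#' @return `load_trained_model` returns the `trained_model`.
#' @export
save_trained_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_trained_model
#' @export
load_trained_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "trained_model")) stop("not a trained_model checkpoint: ", path)
  m
}

#' @rdname save_trained_model
#' @export
save_training_log <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  utils::write.csv(model$history, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.trained_model <- function(x, ...) {
  cat("trained_model:", x$spec$architecture_id,
      "| validation accuracy", sprintf("%.3f", x$validation_accuracy), "\n")
  invisible(x)
}
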