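test_that("capsule network shape chain follows the valid-convolution arithmetic", {
  spec <- build_capsnet()
  # 60 -> 52 (9x9 stride 1, valid) -> 22 (9x9 stride 2, valid)
  expect_equal(trapnet:::conv_out_side(60, 9, 1, 0), 52)
  s <- floor((floor((60 - 9) / 1) + 1 - 9) / 2) + 1
  expect_equal(trapnet:::conv_out_side(52, 9, 2, 0), s)
  expect_equal(spec$primary_grid, 22L)
  expect_equal(spec$primary_types, 32)
  expect_equal(spec$primary_dim, 8L)
  expect_equal(spec$n_primary, 22 * 22 * 32)
  expect_equal(spec$class_dim, 16L)
})

test_that("a capsnet forward pass realizes the declared shapes and bounds", {
  set.seed(1)
  spec <- build_capsnet(conv1_filters = 4, primary_types = 2)
  model <- trapnet:::init_model(spec)
  x <- array(runif(60 * 60 * 2), c(60, 60, 2, 1))
  fwd <- trapnet:::capsnet_forward(model, spec, x, FALSE, 3)
  expect_equal(dim(fwd$conv$out), c(22, 22, 2, 2 * 8))
  expect_equal(fwd$n_caps, 22 * 22 * 2)
  expect_equal(dim(fwd$route$V), c(16, 5, 2))
  lens <- fwd$lens
  expect_true(all(lens >= 0 & lens < 1))   # squash bound on all class capsules
  # coupling rows sum to 1 per input capsule and image
  expect_equal(apply(fwd$route$C, c(1, 3), sum),
               matrix(1, fwd$n_caps, 2), tolerance = 1e-9)
})

test_that("all three architectures emit valid probability vectors in batch order", {
  set.seed(2)
  ds <- tiny_dataset()
  hp <- hyper_params(epochs = 1, batch_size = 4, seed = 1)
  hpc <- hyper_params(epochs = 1, batch_size = 4, seed = 1, routing_iterations = 2)
  specs <- list(build_cnn2(width_scale = 0.25),
                build_cnn13(width_scale = 0.0625),
                build_capsnet(conv1_filters = 2, primary_types = 1,
                              decoder_units = c(4, 6)))
  for (k in seq_along(specs)) {
    m <- train_model(specs[[k]], ds, if (k == 3) hpc else hp)
    p <- predict(m, ds$images)
    expect_equal(dim(p), c(dataset_size(ds), 5))
    expect_true(all(p >= 0))
    expect_equal(rowSums(p), rep(1, nrow(p)), tolerance = 1e-9)
    # batch order preserved: predicting a subset matches the full run
    p2 <- predict(m, ds$images[, , 3:5])
    expect_equal(p2, p[3:5, ], tolerance = 1e-12)
    expect_equal(nrow(m$history), 1)
  }
})

test_that("capsnet probabilities are the normalized class-capsule lengths", {
  set.seed(3)
  spec <- build_capsnet(conv1_filters = 2, primary_types = 1,
                        decoder_units = c(4, 6))
  ds <- tiny_dataset()
  m <- train_model(spec, ds, hyper_params(epochs = 1, batch_size = 4, seed = 1))
  imgs <- ds$images[, , 1:3]
  p <- predict(m, imgs)
  fwd <- trapnet:::capsnet_forward(m$model, spec, trapnet:::as_batch_array(imgs),
                                   FALSE, m$routing_iterations)
  expect_equal(p, t(sweep(fwd$lens, 2, colSums(fwd$lens), `/`)),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("CNN-2 has strictly fewer parameters than CNN-13", {
  expect_lt(param_count(build_cnn2()), param_count(build_cnn13()))
})

test_that("training rejects empty splits and bad hyper-parameters", {
  ds <- tiny_dataset()
  no_val <- dataset_subset(ds, c("train", "test"))
  expect_error(train_model(build_cnn2(width_scale = 0.25), no_val,
                           hyper_params(epochs = 1)), "validation split")
  expect_error(hyper_params(learning_rate = 0), "positive")
  expect_error(hyper_params(batch_size = 0), "positive")
  expect_error(hyper_params(routing_iterations = 0), ">= 1")
})

test_that("fixed seeds reproduce the training trajectory exactly", {
  ds <- tiny_dataset()
  hp <- hyper_params(epochs = 2, batch_size = 4, seed = 42)
  m1 <- train_model(build_cnn2(width_scale = 0.25), ds, hp)
  m2 <- train_model(build_cnn2(width_scale = 0.25), ds, hp)
  expect_identical(m1$history, m2$history)
  expect_equal(predict(m1, ds$images), predict(m2, ds$images), tolerance = 1e-12)
})

test_that("model checkpoints round-trip through a single-file archive", {
  ds <- tiny_dataset()
  m <- train_model(build_cnn2(width_scale = 0.25), ds,
                   hyper_params(epochs = 1, batch_size = 4, seed = 9))
  f <- tempfile(fileext = ".rds")
  save_trained_model(m, f)
  back <- load_trained_model(f)
  expect_equal(predict(back, ds$images), predict(m, ds$images), tolerance = 1e-12)
  expect_identical(back$history, m$history)
  log <- tempfile(fileext = ".csv")
  save_training_log(m, log)
  expect_equal(read.csv(log)$epoch, m$history$epoch)
  unlink(c(f, log))
})
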