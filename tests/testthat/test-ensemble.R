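# lightweight stand-in "trained models" with fixed outputs: predict() is
# dispatched on class trained_model, so give them real structure
fake_model <- function(val_acc, probs_fun) {
  structure(list(spec = list(architecture_id = "cnn2"),
                 validation_accuracy = val_acc,
                 probs_fun = probs_fun),
            class = c("fake_model", "trained_model"))
}

# route predict() through the fake's stored function
predict.fake_model <- function(object, images, ...) object$probs_fun(images)
registerS3method("predict", "fake_model", predict.fake_model)

test_that("ensemble weights are validation accuracies normalized to sum 1", {
  ms <- list(fake_model(0.98, NULL), fake_model(0.90, NULL), fake_model(0.90, NULL))
  E <- build_ensemble(ms)
  expect_equal(E$weights, c(0.98, 0.90, 0.90) / 2.78, tolerance = 1e-12)
  expect_equal(round(E$weights, 4), c(0.3525, 0.3237, 0.3237))
  expect_equal(sum(E$weights), 1)

  E2 <- build_ensemble(list(fake_model(0.8, NULL), fake_model(0.8, NULL)))
  expect_equal(E2$weights, c(0.5, 0.5))

  E3 <- build_ensemble(list(fake_model(0, NULL), fake_model(0.9, NULL)))
  expect_equal(E3$weights, c(0, 1))

  expect_error(build_ensemble(list(fake_model(0.9, NULL))), "at least 2")
  expect_error(build_ensemble(list(fake_model(0, NULL), fake_model(0, NULL))),
               "zero")
  expect_error(build_ensemble(list(fake_model(NULL, NULL), fake_model(0.9, NULL))),
               "validation accuracy")
})

test_that("ensemble prediction is the hand-computed convex combination", {
  p1 <- matrix(c(0.6, 0.1, 0.1, 0.1, 0.1), 1)
  p2 <- matrix(c(0.2, 0.5, 0.1, 0.1, 0.1), 1)
  p3 <- matrix(c(0.1, 0.1, 0.6, 0.1, 0.1), 1)
  ms <- list(fake_model(0.9, function(x) p1),
             fake_model(0.6, function(x) p2),
             fake_model(0.3, function(x) p3))
  E <- build_ensemble(ms)
  w <- c(0.9, 0.6, 0.3) / 1.8
  expect_equal(ensemble_predict(E, array(0, c(60, 60, 1))),
               w[1] * p1 + w[2] * p2 + w[3] * p3, tolerance = 1e-12)
  expect_equal(sum(ensemble_predict(E, array(0, c(60, 60, 1)))), 1)

  # identical members: convexity fixed point
  Eid <- build_ensemble(list(fake_model(0.7, function(x) p1),
                             fake_model(0.7, function(x) p1)))
  expect_equal(ensemble_predict(Eid, array(0, c(60, 60, 1))), p1)

  # degenerate weights (1, 0) reproduce member 1 exactly
  E10 <- build_ensemble(list(fake_model(0.9, function(x) p1),
                             fake_model(0, function(x) p2)))
  expect_equal(ensemble_predict(E10, array(0, c(60, 60, 1))), p1)
})

test_that("member order does not change ensemble predictions", {
  set.seed(1)
  p <- lapply(1:3, function(i) {
    m <- matrix(runif(10 * 5), 10, 5); m / rowSums(m)
  })
  accs <- c(0.9, 0.8, 0.7)
  ms <- Map(function(a, pm) fake_model(a, function(x) pm), accs, p)
  imgs <- array(0, c(60, 60, 10))
  base <- ensemble_predict(build_ensemble(ms), imgs)
  perm <- ensemble_predict(build_ensemble(ms[c(3, 1, 2)]), imgs)
  expect_equal(base, perm, tolerance = 1e-12)
})

test_that("three members enumerate exactly four ensembles", {
  ms <- list(fake_model(0.9, NULL), fake_model(0.8, NULL), fake_model(0.7, NULL))
  ens <- enumerate_ensembles(ms, names = c("A", "B", "C"))
  expect_length(ens, 4)
  expect_identical(names(ens), c("A+B", "A+C", "B+C", "A+B+C"))
  expect_equal(choose(3, 2) + choose(3, 3), 4)
  sizes <- vapply(ens, function(e) length(e$members), numeric(1))
  expect_equal(unname(sizes), c(2, 2, 2, 3))
  # identical members still give 4 structural combinations
  same <- enumerate_ensembles(list(fake_model(0.5, NULL), fake_model(0.5, NULL),
                                   fake_model(0.5, NULL)))
  expect_length(same, 4)
  expect_error(enumerate_ensembles(ms[1:2]), "exactly 3")
})
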