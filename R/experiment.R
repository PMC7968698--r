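#' Hyper-parameter grid over the six searched axes
#'
#' The default grid spans routing iterations (capsule network only),
#' learning rate, batch size, the add-noise flag, epochs, and the
#' augmentation flag, sized so the full cartesian product enumerates
#' exactly 108 combinations: 3 x 3 x 3 x 2 x 2 x 1.
#'
#' @param routing_iterations,learning_rate,batch_size,add_noise,epochs,augmentation
#'   vectors of candidate values, all nonempty.
#' @return A list of class `hyper_grid`.
#' @export
hyper_grid <- function(routing_iterations = c(1L, 3L, 5L),
                       learning_rate = c(1e-3, 3e-4, 1e-4),
                       batch_size = c(32L, 64L, 128L),
                       add_noise = c(TRUE, FALSE),
                       epochs = c(5L, 20L),
                       augmentation = TRUE) {
  axes <- list(routing_iterations = routing_iterations,
               learning_rate = learning_rate, batch_size = batch_size,
               add_noise = add_noise, epochs = epochs,
               augmentation = augmentation)
  if (any(lengths(axes) == 0)) stop("every grid axis must be nonempty")
  structure(axes, class = "hyper_grid")
}

#' Enumerate a hyper-parameter grid
#'
#' Deterministic cartesian product (first axis varying fastest), one row
#' per combination; the row count is the product of the axis lengths.
#'
#' @param grid a [hyper_grid()].
#' @param collapse_routing drop the routing axis (architectures without
#'   routing); duplicate rows collapse.
#' @return A data frame, one combination per row.
#' @export
enumerate_grid <- function(grid, collapse_routing = FALSE) {
  stopifnot(inherits(grid, "hyper_grid"))
  axes <- unclass(grid)
  if (collapse_routing) axes$routing_iterations <- axes$routing_iterations[1]
  out <- expand.grid(axes, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out
}

#' Grid search over training hyper-parameters
#'
#' Trains one model per grid combination and ranks them by validation
#' accuracy (ties broken by fewer epochs, then lower learning rate). For
#' non-capsule architectures the routing axis is collapsed before
#' enumeration, since routing iterations only exist for the capsule
#' network.
#'
#' @param spec a `model_spec`.
#' @param grid a [hyper_grid()].
#' @param dataset a `trap_dataset` with train/val/test splits.
#' @param seed base seed (each combination trains under the same seed so
#'   rankings are reproducible).
#' @param top_k how many top models to retain with parameters (default
#'   10); all results keep their scores.
#' @param verbose print progress.
#' @return A list with `results` (data frame of combinations + validation
#'   accuracy, ranked) and `top` (list of the `top_k` best
#'   `trained_model`s in rank order).
#' @export
grid_search <- function(spec, grid, dataset, seed = 1L, top_k = 10L,
                        verbose = FALSE) {
  combos <- enumerate_grid(grid, collapse_routing =
                             spec$architecture_id != "capsnet")
  if (nrow(combos) == 0) stop("empty hyper-parameter grid")
  models <- vector("list", nrow(combos))
  val_acc <- numeric(nrow(combos))
  for (r in seq_len(nrow(combos))) {
    hp <- hyper_params(routing_iterations = combos$routing_iterations[r],
                       learning_rate = combos$learning_rate[r],
                       batch_size = combos$batch_size[r],
                       add_noise = combos$add_noise[r],
                       epochs = combos$epochs[r],
                       augmentation = combos$augmentation[r],
                       seed = seed)
    m <- train_model(spec, dataset, hp)
    models[[r]] <- m
    val_acc[r] <- m$validation_accuracy
    if (verbose) {
      message(sprintf("combo %d/%d val_acc %.3f", r, nrow(combos), val_acc[r]))
    }
  }
  results <- cbind(combos, val_acc = val_acc, combo = seq_len(nrow(combos)))
  ord <- order(-results$val_acc, results$epochs, results$learning_rate)
  results <- results[ord, , drop = FALSE]
  rownames(results) <- NULL
  list(results = results,
       top = models[results$combo[seq_len(min(top_k, nrow(results)))]])
}

#' Configuration for the full model comparison
#'
#' Defaults are sized for a single-CPU "smoke scale" run: reduced channel
#' widths, few epochs, and an augmentation multiplier of 2. The reference
#' full-scale settings (width scale 1, 20 epochs, multiplier 32) are the
#' same code with different numbers.
#'
#' @param width_scale channel-width multiplier for the two CNNs.
#' @param capsnet_conv1_filters,capsnet_primary_types capsule-network
#'   widths used for training runs.
#' @param epochs,cnn2_epochs,capsnet_epochs training epochs per
#'   architecture (the capsule network is the most expensive member; the
#'   2-layer CNN is cheap enough for the full 5 epochs).
#' @param cnn2_aug_multiplier augmentation multiplier for the CNN-2 arm
#'   (its augmented run benefits from the extra optimizer steps and stays
#'   cheap).
#' @param learning_rate,batch_size Adam settings for the two CNNs.
#' @param capsnet_learning_rate,capsnet_batch_size Adam settings for the
#'   capsule network.
#' @param feature_norm feed the CNNs feature-wise centered/standardized
#'   images (the capsule network always trains on raw intensities so its
#'   decoder can reconstruct them).
#' @param routing_iterations capsule routing iterations.
#' @param aug_multiplier augmentation multiplier for with-augmentation
#'   runs.
#' @param seed base seed.
#' @return A list of class `comparison_config`.
#' @export
comparison_config <- function(width_scale = 0.25,
                              capsnet_conv1_filters = 10,
                              capsnet_primary_types = 8,
                              epochs = 4L, cnn2_epochs = 5L,
                              capsnet_epochs = 3L,
                              cnn2_aug_multiplier = 3L,
                              learning_rate = 1.5e-3,
                              capsnet_learning_rate = 1e-3,
                              batch_size = 8L, capsnet_batch_size = 24L,
                              routing_iterations = 3L,
                              feature_norm = TRUE,
                              aug_multiplier = 2L, seed = 1L) {
  structure(list(width_scale = width_scale,
                 capsnet_conv1_filters = capsnet_conv1_filters,
                 capsnet_primary_types = capsnet_primary_types,
                 epochs = as.integer(epochs),
                 cnn2_epochs = as.integer(cnn2_epochs),
                 capsnet_epochs = as.integer(capsnet_epochs),
                 cnn2_aug_multiplier = as.integer(cnn2_aug_multiplier),
                 learning_rate = learning_rate,
                 capsnet_learning_rate = capsnet_learning_rate,
                 batch_size = as.integer(batch_size),
                 capsnet_batch_size = as.integer(capsnet_batch_size),
                 routing_iterations = as.integer(routing_iterations),
                 feature_norm = feature_norm,
                 aug_multiplier = as.integer(aug_multiplier),
                 seed = as.integer(seed)),
            class = "comparison_config")
}

eval_on_test <- function(model_or_ensemble, test_ds) {
  probs <- if (inherits(model_or_ensemble, "ensemble_model")) {
    ensemble_predict(model_or_ensemble, test_ds$images)
  } else {
    predict(model_or_ensemble, test_ds$images)
  }
  pred5 <- argmax_label(probs, 5)
  C5 <- confusion(test_ds$labels, pred5, 5)
  C4 <- reduce_confusion(C5)
  m4 <- compute_metrics(C4)
  n_correct <- sum(diag(C4))
  list(confusion5 = C5, confusion4 = C4, metrics4 = m4,
       accuracy5 = sum(diag(C5)) / sum(C5),
       accuracy4 = m4$overall_accuracy,
       n_predicted_correct = n_correct,
       n_mispredicted = sum(C4) - n_correct,
       dd_du = data.frame(
         category = c("mddC", "mduC"),
         correct = c(C5["mddC", "mddC"], C5["mduC", "mduC"]),
         mispredicted = c(sum(C5["mddC", ]) - C5["mddC", "mddC"],
                          sum(C5["mduC", ]) - C5["mduC", "mduC"])))
}

#' Run the full model comparison
#'
#' Trains CNN-2, CNN-13 and the capsule network with and without
#' augmentation on the dataset's training split, builds all four
#' validation-accuracy-weighted ensembles from the with-augmentation
#' models, and evaluates every model and ensemble once on the common test
#' split in both category spaces. The test split is used only for these
#' final numbers, never for selection.
#'
#' @param dataset a `trap_dataset` with train/val/test splits.
#' @param config a [comparison_config()].
#' @param verbose print training progress.
#' @return A list of class `experiment_report`: `models` (per
#'   architecture, `with_aug`/`without_aug` evaluation lists), `ensembles`
#'   (4 evaluation lists), `test_size`, and `config`.
#' @export
run_comparison <- function(dataset, config = comparison_config(),
                           verbose = FALSE) {
  stopifnot(inherits(dataset, "trap_dataset"))
  for (sp in c("train", "val", "test")) {
    if (!any(dataset$split == sp)) stop("dataset is missing the ", sp, " split")
  }
  test_ds <- dataset_subset(dataset, "test")
  specs <- list(
    cnn2 = build_cnn2(width_scale = config$width_scale),
    cnn13 = build_cnn13(width_scale = config$width_scale),
    capsnet = build_capsnet(conv1_filters = config$capsnet_conv1_filters,
                            primary_types = config$capsnet_primary_types))
  models <- list()
  for (arch in names(specs)) {
    caps <- arch == "capsnet"
    models[[arch]] <- list()
    for (aug in c(FALSE, TRUE)) {
      # feature-wise normalization feeds the CNNs; the capsule network
      # trains on raw [0,1] images so its decoder can reconstruct them
      hp <- hyper_params(routing_iterations = config$routing_iterations,
                         learning_rate = if (caps) config$capsnet_learning_rate
                                         else config$learning_rate,
                         batch_size = if (caps) config$capsnet_batch_size
                                      else config$batch_size,
                         epochs = if (caps) config$capsnet_epochs
                                  else if (arch == "cnn2") config$cnn2_epochs
                                  else config$epochs,
                         augmentation = aug,
                         # orientation-preserving, nuisance-matched
                         # augmentation: vertical flips would swap
                         # mduC/mddC under a fixed 5-space label, and
                         # transform magnitudes stay within the
                         # generator's own nuisance envelope (traps are
                         # upright in the chip, so rotations are small)
                         aug_cfg = augmentation_config(
                           rotation_range = 8, width_shift = 0.05,
                           height_shift = 0.05,
                           brightness_range = c(0.9, 1.1),
                           vertical_flip = FALSE, noise_sigma = 0.02,
                           multiplier = if (arch == "cnn2")
                             config$cnn2_aug_multiplier
                           else config$aug_multiplier,
                           featurewise_center = config$feature_norm && !caps,
                           featurewise_std_normalization = config$feature_norm && !caps),
                         seed = config$seed)
      if (verbose) message("training ", arch, if (aug) " (augmented)" else "")
      tm <- train_model(specs[[arch]], dataset, hp, verbose = verbose)
      key <- if (aug) "with_aug" else "without_aug"
      models[[arch]][[key]] <- tm
    }
  }
  report <- list(models = list(), ensembles = list(),
                 test_size = dataset_size(test_ds), config = config)
  for (arch in names(models)) {
    report$models[[arch]] <- list(
      without_aug = eval_on_test(models[[arch]]$without_aug, test_ds),
      with_aug = eval_on_test(models[[arch]]$with_aug, test_ds))
    report$models[[arch]]$validation_accuracy <-
      models[[arch]]$with_aug$validation_accuracy
  }
  aug_members <- lapply(models, `[[`, "with_aug")
  ens <- enumerate_ensembles(unname(aug_members), names = names(models))
  for (nm in names(ens)) {
    report$ensembles[[nm]] <- eval_on_test(ens[[nm]], test_ds)
    report$ensembles[[nm]]$weights <- ens[[nm]]$weights
  }
  report$trained <- list(singles = models, ensembles = ens)
  class(report) <- "experiment_report"
  report
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("experiment_report | test size", x$test_size, "\n")
  for (arch in names(x$models)) {
    cat(sprintf("  %-8s acc4 without aug %.4f | with aug %.4f\n", arch,
                x$models[[arch]]$without_aug$accuracy4,
                x$models[[arch]]$with_aug$accuracy4))
  }
  for (nm in names(x$ensembles)) {
    cat(sprintf("  ensemble %-20s acc4 %.4f\n", nm, x$ensembles[[nm]]$accuracy4))
  }
  invisible(x)
}
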