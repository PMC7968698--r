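#' Confusion matrix over the 5- or 4-category space
#'
#' Entry `(a, b)` counts items with true category `a` predicted `b`, in
#' canonical category order.
#'
#' @param true_labels,predicted_labels equal-length character vectors of
#'   labels in the chosen space.
#' @param space 5 (computed categories) or 4 (biological categories).
#' @return A square integer matrix with `true` rows and `predicted`
#'   columns.
#' @export
confusion <- function(true_labels, predicted_labels, space = 5) {
  if (length(true_labels) != length(predicted_labels)) {
    stop("label sequences differ in length (", length(true_labels), " vs ",
         length(predicted_labels), ")")
  }
  lv <- if (space == 5) category5_levels() else category4_levels()
  if (space == 5) {
    assert_category5(true_labels); assert_category5(predicted_labels)
  } else {
    assert_category4(true_labels); assert_category4(predicted_labels)
  }
  C <- table(factor(true_labels, levels = lv),
             factor(predicted_labels, levels = lv))
  C <- unclass(as.matrix(C))
  dimnames(C) <- list(true = lv, predicted = lv)
  C
}

#' Per-category and overall performance metrics
#'
#' For each category `c`, in one-vs-rest terms over the confusion matrix:
#' accuracy `(TP+TN)/(TP+TN+FP+FN)`, precision `TP/(TP+FP)`, recall
#' `TP/(TP+FN)` and `F1 = 2PR/(P+R)`. The per-category accuracy includes
#' the TN term (the one-vs-rest reading in which that term is meaningful);
#' overall accuracy is the trace over the total. Ratios with a zero
#' denominator are reported as 0 and flagged in the `undefined` column.
#'
#' @param C a square confusion matrix (counts, true rows x predicted
#'   columns).
#' @return A list of class `metrics_report`: `per_category` data frame
#'   (category, accuracy, precision, recall, f1, undefined), `overall_accuracy`,
#'   `macro_precision`, `macro_recall`, `total`.
#' @export
compute_metrics <- function(C) {
  C <- as.matrix(C)
  stopifnot(nrow(C) == ncol(C))
  total <- sum(C)
  if (total == 0) stop("empty confusion matrix")
  lv <- rownames(C)
  if (is.null(lv)) lv <- paste0("cat", seq_len(nrow(C)))
  per <- data.frame(category = lv, accuracy = 0, precision = 0, recall = 0,
                    f1 = 0, undefined = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(C))) {
    TP <- C[i, i]
    FN <- sum(C[i, ]) - TP
    FP <- sum(C[, i]) - TP
    TN <- total - TP - FN - FP
    per$accuracy[i] <- (TP + TN) / total
    if (TP + FP > 0) per$precision[i] <- TP / (TP + FP) else per$undefined[i] <- TRUE
    if (TP + FN > 0) per$recall[i] <- TP / (TP + FN) else per$undefined[i] <- TRUE
    pr <- per$precision[i] + per$recall[i]
    per$f1[i] <- if (pr > 0) 2 * per$precision[i] * per$recall[i] / pr else 0
  }
  structure(list(per_category = per,
                 overall_accuracy = sum(diag(C)) / total,
                 macro_precision = mean(per$precision),
                 macro_recall = mean(per$recall),
                 total = total),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("overall accuracy %.4f (n = %d)\n", x$overall_accuracy, x$total))
  print(x$per_category, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Write metrics and confusion matrices to CSV
#'
#' @param report a `metrics_report`.
#' @param C the confusion matrix it came from.
#' @param dir output directory (created if needed).
#' @param prefix file name prefix.
#' @export
write_metrics <- function(report, C, dir, prefix = "metrics") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(report$per_category,
                   file.path(dir, paste0(prefix, "_per_category.csv")),
                   row.names = FALSE)
  utils::write.csv(as.data.frame.matrix(C),
                   file.path(dir, paste0(prefix, "_confusion.csv")))
  invisible(dir)
}

#' Export misclassified images
#'
#' Writes every test item whose 4-space prediction differs from its
#' 4-space truth as a PGM named `<idx>_<true>-as-<predicted>.pgm`, plus a
#' manifest of the (true, predicted) pairs.
#'
#' @param ds a `trap_dataset` (5-space labels).
#' @param probs an N x 5 probability matrix from [predict.trained_model()]
#'   or [ensemble_predict()].
#' @param out_dir output directory.
#' @return Data frame manifest (possibly empty) with columns `path`,
#'   `true4`, `predicted4`, `true5`, `predicted5`.
#' @export
export_misclassified <- function(ds, probs, out_dir) {
  stopifnot(inherits(ds, "trap_dataset"), nrow(probs) == dataset_size(ds))
  ok <- tryCatch({
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    file.access(out_dir, 2) == 0
  }, error = function(e) FALSE)
  if (!ok) stop("output directory is not writable: ", out_dir)
  pred5 <- argmax_label(probs, 5)
  pred4 <- merge_label(pred5)
  true4 <- merge_label(ds$labels)
  bad <- which(pred4 != true4)
  man <- data.frame(path = character(0), true4 = character(0),
                    predicted4 = character(0), true5 = character(0),
                    predicted5 = character(0), stringsAsFactors = FALSE)
  for (i in bad) {
    fn <- sprintf("%04d_%s-as-%s.pgm", i, true4[i], pred4[i])
    write_pgm(ds$images[, , i], file.path(out_dir, fn))
    man[nrow(man) + 1L, ] <- list(fn, true4[i], pred4[i], ds$labels[i], pred5[i])
  }
  utils::write.csv(man, file.path(out_dir, "misclassified.csv"), row.names = FALSE)
  man
}
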