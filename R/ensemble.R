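#' Validation-accuracy-weighted classifier ensemble
#'
#' Combines two or more trained models by convex combination of their
#' probability vectors, with weights proportional to each member's
#' overall validation-set accuracy (normalized to sum to 1).
#'
#' @param members list of `trained_model` objects (>= 2), each carrying a
#'   recorded `validation_accuracy`.
#' @param names optional member names (defaults to architecture ids).
#' @return A list of class `ensemble_model` with `members` and `weights`.
#' @export
build_ensemble <- function(members, names = NULL) {
  if (length(members) < 2) stop("an ensemble needs at least 2 members")
  acc <- vapply(members, function(m) {
    if (is.null(m$validation_accuracy) || !is.finite(m$validation_accuracy)) {
      stop("every member needs a recorded validation accuracy")
    }
    m$validation_accuracy
  }, numeric(1))
  if (sum(acc) <= 0) stop("all member validation accuracies are zero")
  if (is.null(names)) {
    names <- vapply(members, function(m) m$spec$architecture_id, character(1))
  }
  structure(list(members = members, weights = acc / sum(acc),
                 member_names = names, member_accuracies = acc),
            class = "ensemble_model")
}

#' Predict with an ensemble
#'
#' Per image, the ensemble output is the weighted average
#' `sum_m w_m * p_m` of the member probability vectors — a convex
#' combination, hence itself a valid probability vector. The 4-space
#' prediction is obtained by [merge_probs()] followed by argmax.
#'
#' @param E an `ensemble_model`.
#' @param images images accepted by [predict.trained_model()].
#' @return N x 5 probability matrix.
#' @export
ensemble_predict <- function(E, images) {
  stopifnot(inherits(E, "ensemble_model"))
  out <- NULL
  for (m in seq_along(E$members)) {
    p <- predict(E$members[[m]], images)
    if (is.null(out)) {
      out <- E$weights[m] * p
    } else {
      if (!all(dim(p) == dim(out))) stop("member output shape mismatch")
      out <- out + E$weights[m] * p
    }
  }
  out
}

#' Enumerate all ensembles of three members
#'
#' Three members admit exactly four combinations of size >= 2: the three
#' pairs and the full trio, returned in deterministic order (AB, AC, BC,
#' ABC).
#'
#' @param members list of exactly 3 `trained_model` objects.
#' @param names optional member names.
#' @return List of 4 `ensemble_model` objects, named by their members.
#' @export
enumerate_ensembles <- function(members, names = NULL) {
  if (length(members) != 3) stop("expected exactly 3 members")
  if (is.null(names)) {
    names <- vapply(members, function(m) m$spec$architecture_id, character(1))
  }
  combos <- list(c(1, 2), c(1, 3), c(2, 3), c(1, 2, 3))
  out <- lapply(combos, function(ix) build_ensemble(members[ix], names[ix]))
  names(out) <- vapply(combos, function(ix) paste(names[ix], collapse = "+"),
                       character(1))
  out
}

#' @export
print.ensemble_model <- function(x, ...) {
  cat("ensemble_model:", paste(x$member_names, collapse = " + "), "\n")
  cat("weights:", paste(sprintf("%.4f", x$weights), collapse = ", "), "\n")
  invisible(x)
}
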