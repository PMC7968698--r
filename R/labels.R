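#' Category sets for trap classification
#'
#' Trap sub-images are classified into five *computed* categories: `nC`
#' (empty trap), `mC` (single mother cell), `mduC` (mother plus a daughter
#' above her), `mddC` (mother plus a daughter below her), and `exC` (a
#' crowded trap with more than two cells). Because `mduC` and `mddC`
#' describe the same biological situation (a mother with one daughter),
#' they merge into a single biological category `mdC`, giving the four
#' *biological* categories `nC`, `mC`, `mdC`, `exC`.
#'
#' The canonical order is fixed (`nC`, `mC`, `mduC`, `mddC`, `exC` and
#' `nC`, `mC`, `mdC`, `exC`) and used for every probability vector and
#' confusion matrix in the package.
#'
#' @return A character vector of category names in canonical order.
#' @export
category5_levels <- function() c("nC", "mC", "mduC", "mddC", "exC")

#' @rdname category5_levels
#' @export
category4_levels <- function() c("nC", "mC", "mdC", "exC")

assert_category5 <- function(l) {
  if (!all(l %in% category5_levels())) {
    bad <- setdiff(unique(l), category5_levels())
    stop("unknown 5-space label(s): ", paste(bad, collapse = ", "))
  }
  invisible(l)
}

assert_category4 <- function(l) {
  if (!all(l %in% category4_levels())) {
    bad <- setdiff(unique(l), category4_levels())
    stop("unknown 4-space label(s): ", paste(bad, collapse = ", "))
  }
  invisible(l)
}

#' Merge computed labels into biological labels
#'
#' Sends `mddC` and `mduC` to `mdC`; `nC`, `mC` and `exC` map to
#' themselves. Vectorised.
#'
#' @param labels character vector (or factor) of 5-space labels.
#' @return Character vector of 4-space labels.
#' @examples
#' merge_label(c("mddC", "mduC", "nC"))
#' @export
merge_label <- function(labels) {
  labels <- as.character(labels)
  assert_category5(labels)
  ifelse(labels %in% c("mddC", "mduC"), "mdC", labels)
}

#' Merge a 5-category probability vector into 4-category space
#'
#' The `mdC` entry is the sum of the `mddC` and `mduC` entries; the other
#' entries are copied. Input must be a valid probability vector over the
#' canonical 5-space order.
#'
#' @param p numeric vector of length 5 (or a matrix with 5 columns, one
#'   row per image), nonnegative, summing to 1 within `1e-9` per row.
#' @return A vector of length 4 (or matrix with 4 columns) in canonical
#'   4-space order.
#' @export
merge_probs <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 5)
    if (any(p < -1e-12)) stop("probability entries must be nonnegative")
    if (any(abs(rowSums(p) - 1) > 1e-9)) {
      stop("probability rows must sum to 1 within 1e-9")
    }
    out <- cbind(p[, 1L], p[, 2L], p[, 3L] + p[, 4L], p[, 5L])
    colnames(out) <- category4_levels()
    return(out)
  }
  if (length(p) != 5) stop("expected a probability vector of length 5")
  if (any(p < -1e-12)) stop("probability entries must be nonnegative")
  if (abs(sum(p) - 1) > 1e-9) stop("probabilities must sum to 1 within 1e-9")
  out <- c(p[1L], p[2L], p[3L] + p[4L], p[5L])
  names(out) <- category4_levels()
  out
}

#' Reduce a 5-space confusion matrix to 4-space
#'
#' The `mddC` and `mduC` rows are summed and the corresponding columns are
#' summed, so confusions between the two daughter orientations become
#' correct `mdC` calls. The grand total is preserved.
#'
#' @param C a 5x5 nonnegative count matrix with rows = true and columns =
#'   predicted categories in canonical order (dimnames optional).
#' @return A 4x4 count matrix with canonical 4-space dimnames.
#' @export
reduce_confusion <- function(C) {
  C <- as.matrix(C)
  stopifnot(nrow(C) == 5, ncol(C) == 5)
  if (any(C < 0)) stop("confusion counts must be nonnegative")
  M <- merge_matrix5to4()
  out <- t(M) %*% C %*% M
  dimnames(out) <- list(true = category4_levels(),
                        predicted = category4_levels())
  out
}

# 5x4 indicator matrix of the merge map (column-stochastic on rows)
merge_matrix5to4 <- function() {
  M <- matrix(0, 5, 4, dimnames = list(category5_levels(), category4_levels()))
  for (l in category5_levels()) M[l, merge_label(l)] <- 1
  M
}

#' Deterministic argmax over category probabilities
#'
#' Returns the category whose probability is maximal; ties are broken by
#' canonical category order (the earliest category wins), so results are
#' deterministic.
#'
#' @param p numeric vector or matrix of per-category scores (5 or 4
#'   columns).
#' @param space 5 or 4, selecting the label space.
#' @return Character vector of predicted labels.
#' @export
argmax_label <- function(p, space = 5) {
  lv <- if (space == 5) category5_levels() else category4_levels()
  if (!is.matrix(p)) p <- matrix(p, nrow = 1)
  stopifnot(ncol(p) == length(lv))
  lv[apply(p, 1L, which.max)]
}
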