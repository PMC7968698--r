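#' Capsule squash nonlinearity
#'
#' Maps a vector `s` to `(||s||^2 / (1 + ||s||^2)) * s / ||s||`: the
#' direction is preserved and the length is squashed into `[0, 1)`, so a
#' capsule's output length can be read as the probability that the feature
#' it represents is present. The zero vector maps to zero. When `s` is a
#' matrix, each column is squashed independently.
#'
#' @param s numeric vector, or matrix with one vector per column.
#' @param eps numerical guard added under the square root when dividing by
#'   the norm; default `1e-12`.
#' @return Squashed vector/matrix of the same shape.
#' @examples
#' squash(c(3, 4))        # length 25/26 along (0.6, 0.8)
#' @export
squash <- function(s, eps = 1e-12) {
  if (!all(is.finite(s))) stop("squash: non-finite input")
  if (is.matrix(s)) {
    n2 <- colSums(s * s)
    scale <- n2 / (1 + n2) / sqrt(n2 + eps)
    return(sweep(s, 2, scale, `*`))
  }
  n2 <- sum(s * s)
  s * (n2 / (1 + n2) / sqrt(n2 + eps))
}

# d v / d s for one capsule: J = a/|s| (I - ssT/|s|^2) + (2/(1+|s|^2)^2 - a/|s|... )
# implemented directly from v = f(n) * s/n with f(n) = n^2/(1+n^2):
# J = f(n)/n * I + (f'(n) - f(n)/n) * s sT / n^2,  f'(n) = 2n/(1+n^2)^2
squash_jacobian_apply <- function(s, g, eps = 1e-12) {
  n2 <- sum(s * s)
  n <- sqrt(n2 + eps)
  fn <- n2 / (1 + n2)
  fp <- 2 * n / (1 + n2)^2
  (fn / n) * g + ((fp - fn / n) / n2) * s * sum(s * g)
}

#' Affine prediction vectors of a capsule layer
#'
#' Computes the prediction each input capsule makes for each parent
#' capsule: `u_hat[j|i] = W[i,j] %*% u[i]`.
#'
#' @param W list-of-lists (or 4-d array `dim = c(d_out, d_in, n_in,
#'   n_parent)`) of weight matrices, one `d_out x d_in` matrix per
#'   `(i, j)` pair.
#' @param U numeric matrix `d_in x n_in`, one input capsule per column.
#' @return A 3-d array `dim = c(d_out, n_in, n_parent)` of predictions.
#' @export
predict_vectors <- function(W, U) {
  if (is.list(W)) {
    n_in <- length(W)
    n_parent <- length(W[[1]])
    d_out <- nrow(W[[1]][[1]])
    A <- array(0, c(d_out, ncol(W[[1]][[1]]), n_in, n_parent))
    for (i in seq_len(n_in)) for (j in seq_len(n_parent)) A[, , i, j] <- W[[i]][[j]]
    W <- A
  }
  stopifnot(length(dim(W)) == 4)
  d_out <- dim(W)[1]; d_in <- dim(W)[2]; n_in <- dim(W)[3]; n_parent <- dim(W)[4]
  if (nrow(U) != d_in || ncol(U) != n_in) {
    stop("dimension mismatch: U is ", nrow(U), "x", ncol(U),
         " but W expects d_in=", d_in, ", n_in=", n_in)
  }
  u_hat <- array(0, c(d_out, n_in, n_parent))
  for (j in seq_len(n_parent)) {
    acc <- matrix(0, d_out, n_in)
    for (k in seq_len(d_in)) {
      Wk <- matrix(W[, k, , j], d_out, n_in)
      acc <- acc + Wk * rep(U[k, ], each = d_out)
    }
    u_hat[, , j] <- acc
  }
  u_hat
}

#' Dynamic routing between capsule layers
#'
#' Routing-by-agreement: logits `b[i,j]` start at zero; each iteration
#' computes coupling coefficients `C[i, ] = softmax(b[i, ])` over parents,
#' parent inputs `S[,j] = sum_i C[i,j] * u_hat[,i,j]`, squashed outputs
#' `V[,j] = squash(S[,j])`, and (on all but the last iteration) increments
#' the logits by the agreement `u_hat[,i,j] . V[,j]`.
#'
#' @param u_hat 3-d array `dim = c(d_out, n_in, n_parent)` of prediction
#'   vectors (see [predict_vectors()]).
#' @param iterations number of routing iterations, >= 1.
#' @return A list with `C` (`n_in x n_parent` couplings, rows summing to
#'   1), `V` (`d_out x n_parent` parent outputs), `S` (pre-squash parent
#'   inputs), and `B` (final logits).
#' @export
dynamic_routing <- function(u_hat, iterations = 3) {
  stopifnot(length(dim(u_hat)) == 3)
  if (iterations < 1) stop("routing needs at least 1 iteration")
  d_out <- dim(u_hat)[1]; n_in <- dim(u_hat)[2]; n_parent <- dim(u_hat)[3]
  B <- matrix(0, n_in, n_parent)
  C <- S <- V <- NULL
  for (it in seq_len(iterations)) {
    C <- softmax_rows(B)
    S <- matrix(0, d_out, n_parent)
    for (j in seq_len(n_parent)) {
      S[, j] <- matrix(u_hat[, , j], d_out, n_in) %*% C[, j]
    }
    V <- squash(S)
    if (it < iterations) {
      for (j in seq_len(n_parent)) {
        B[, j] <- B[, j] + crossprod(matrix(u_hat[, , j], d_out, n_in), V[, j])
      }
    }
  }
  list(C = C, V = V, S = S, B = B)
}

softmax_rows <- function(B) {
  e <- exp(B - apply(B, 1, max))
  e / rowSums(e)
}
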