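# Independent brute-force oracles used across the test files. These stay
# deliberately naive (loops, flood fill) so they cannot share bugs with
# the vectorized implementations they check.

# 4-connected component labelling of a logical matrix by flood fill
cc_label <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i in seq_len(nrow(mask))) {
    for (j in seq_len(ncol(mask))) {
      if (mask[i, j] && lab[i, j] == 0L) {
        cur <- cur + 1L
        stack <- list(c(i, j))
        while (length(stack)) {
          p <- stack[[length(stack)]]
          stack[[length(stack)]] <- NULL
          if (p[1] < 1 || p[2] < 1 || p[1] > nrow(mask) || p[2] > ncol(mask)) next
          if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
          lab[p[1], p[2]] <- cur
          stack <- c(stack, list(c(p[1] - 1, p[2]), c(p[1] + 1, p[2]),
                                 c(p[1], p[2] - 1), c(p[1], p[2] + 1)))
        }
      }
    }
  }
  lab
}

cc_count <- function(mask) max(cc_label(mask))

# centroid rows of each component, in component-label order
cc_centroid_rows <- function(mask) {
  lab <- cc_label(mask)
  vapply(seq_len(max(lab)), function(k) mean(which(lab == k, arr.ind = TRUE)[, 1]),
         numeric(1))
}

# dictionary-counting confusion oracle
confusion_oracle <- function(true, pred, levels) {
  C <- matrix(0L, length(levels), length(levels), dimnames = list(levels, levels))
  for (i in seq_along(true)) C[true[i], pred[i]] <- C[true[i], pred[i]] + 1L
  C
}

# element-wise loop oracle for prediction vectors
predict_vectors_oracle <- function(W, U) {
  d <- dim(W)
  out <- array(0, c(d[1], d[3], d[4]))
  for (i in seq_len(d[3])) for (j in seq_len(d[4])) {
    for (a in seq_len(d[1])) {
      s <- 0
      for (b in seq_len(d[2])) s <- s + W[a, b, i, j] * U[b, i]
      out[a, i, j] <- s
    }
  }
  out
}

squash_oracle <- function(s) {
  n2 <- sum(s^2)
  if (n2 == 0) return(s * 0)
  (n2 / (1 + n2)) * s / sqrt(n2)
}

# plain-loop dynamic routing oracle
routing_oracle <- function(u_hat, iterations) {
  d_out <- dim(u_hat)[1]; n_in <- dim(u_hat)[2]; K <- dim(u_hat)[3]
  B <- matrix(0, n_in, K)
  for (it in seq_len(iterations)) {
    C <- matrix(0, n_in, K)
    for (i in seq_len(n_in)) {
      e <- exp(B[i, ] - max(B[i, ]))
      C[i, ] <- e / sum(e)
    }
    S <- matrix(0, d_out, K)
    for (j in seq_len(K)) for (i in seq_len(n_in)) {
      S[, j] <- S[, j] + C[i, j] * u_hat[, i, j]
    }
    V <- matrix(0, d_out, K)
    for (j in seq_len(K)) V[, j] <- squash_oracle(S[, j])
    if (it < iterations) {
      for (i in seq_len(n_in)) for (j in seq_len(K)) {
        B[i, j] <- B[i, j] + sum(u_hat[, i, j] * V[, j])
      }
    }
  }
  list(C = C, V = V, S = S)
}

# per-cell arithmetic metrics oracle
metrics_oracle <- function(C) {
  total <- sum(C)
  out <- data.frame(accuracy = numeric(nrow(C)), precision = numeric(nrow(C)),
                    recall = numeric(nrow(C)), f1 = numeric(nrow(C)))
  for (i in seq_len(nrow(C))) {
    TP <- C[i, i]; FN <- sum(C[i, ]) - TP; FP <- sum(C[, i]) - TP
    TN <- total - TP - FN - FP
    out$accuracy[i] <- (TP + TN) / total
    out$precision[i] <- if (TP + FP > 0) TP / (TP + FP) else 0
    out$recall[i] <- if (TP + FN > 0) TP / (TP + FN) else 0
    pr <- out$precision[i] + out$recall[i]
    out$f1[i] <- if (pr > 0) 2 * out$precision[i] * out$recall[i] / pr else 0
  }
  out
}

# small dataset shared by several test files (cached per session)
tiny_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- generate_dataset(12, scene_params(), c(0.5, 0.25, 0.25),
                                 seed = 99)
    }
    cache
  }
})
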