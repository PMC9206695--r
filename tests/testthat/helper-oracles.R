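# Independent oracles used to cross-check the implementation.

# Benjamini-Hochberg step-up, evaluated literally from the definition:
# q_(i) = min_{j >= i} m p_(j) / j, capped at 1, mapped back to input order.
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    qs[i] <- min(1, min(m * ps[js] / js))
  }
  out <- numeric(m)
  out[o] <- qs
  out
}

# Pearson r from the covariance/SD definition.
pearson_bruteforce <- function(x, y) {
  dx <- x - mean(x)
  dy <- y - mean(y)
  sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2))
}

# Joint O2PLS loadings in the nx = ny = 0 reduction, via brute-force
# eigendecomposition of the squared cross-covariance (independent of the
# package's svd route): W = eigenvectors of (X'Y)(X'Y)', C_k proportional
# to (X'Y)' w_k.
plssvd_oracle <- function(X, Y, n) {
  M <- t(X) %*% Y
  W <- eigen(M %*% t(M), symmetric = TRUE)$vectors[, seq_len(n), drop = FALSE]
  C <- matrix(0, ncol(Y), n)
  for (k in seq_len(n)) {
    ck <- t(M) %*% W[, k]
    C[, k] <- ck / sqrt(sum(ck^2))
  }
  list(W = W, C = C)
}

# align the sign of each column of A to the matching column of B
align_columns <- function(A, B) {
  for (k in seq_len(ncol(A))) {
    if (sum(A[, k] * B[, k]) < 0) A[, k] <- -A[, k]
  }
  A
}

# small replicate-level concentration table used across ha_quant tests
toy_replicate_ha <- function() {
  v <- rbind(
    CompA = c(10, 10, 10, 1, 2, 3),
    CompB = c(NA, NA, NA, 5, NA, 7)
  )
  colnames(v) <- c("D0R1", "D0R2", "D0R3", "D2R1", "D2R2", "D2R3")
  ha_table(replicate_values = v)
}
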