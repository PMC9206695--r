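# Two-way orthogonal PLS (O2PLS): joint covarying parts, block-specific
# orthogonal parts, residuals; plus a permutation null over joint loadings
# for variable selection.

#' Scaling specification for O2PLS preprocessing
#'
#' The default mode mirrors the study's preprocessing: both blocks are
#' mean-centered by feature, the metabolite (Y) block is scaled to unit
#' variance per feature, and each block is then scaled to a total sum of
#' squares of 1 so neither block dominates the joint fit. The alternative
#' z-score mode centers and unit-variance-scales every column of both
#' blocks.
#'
#' @param center Mean-center every column of both blocks.
#' @param unit_variance_y Scale Y columns to unit variance.
#' @param equal_total_ssq Scale each block to total sum of squares 1.
#' @param zscore_columns Alternative mode: z-score every column of both
#'   blocks (mutually exclusive with the unit-variance-Y / equal-SSQ mode).
#' @return A list of class \code{scaling_spec}.
#' @export
scaling_spec <- function(center = TRUE, unit_variance_y = TRUE,
                         equal_total_ssq = TRUE, zscore_columns = FALSE) {
  if (zscore_columns && (unit_variance_y || equal_total_ssq)) {
    stop("zscore_columns is an alternative mode; disable unit_variance_y ",
         "and equal_total_ssq to use it", call. = FALSE)
  }
  structure(list(center = center, unit_variance_y = unit_variance_y,
                 equal_total_ssq = equal_total_ssq,
                 zscore_columns = zscore_columns),
            class = "scaling_spec")
}

scale_block <- function(M, center, unit_variance, equal_total_ssq) {
  if (nrow(M) < 2) stop("need at least 2 samples", call. = FALSE)
  if (center) M <- sweep(M, 2, colMeans(M), "-")
  if (unit_variance) {
    sds <- apply(M, 2, stats::sd)
    zero <- sds == 0
    if (any(zero)) {
      stop("zero-variance column(s) under variance scaling: ",
           paste(colnames(M)[zero], collapse = ", "), call. = FALSE)
    }
    M <- sweep(M, 2, sds, "/")
  }
  if (equal_total_ssq) {
    ssq <- sum(M^2)
    if (ssq == 0) stop("block is identically zero", call. = FALSE)
    M <- M / sqrt(ssq)
  }
  M
}

#' Preprocess an X/Y block pair for O2PLS
#'
#' @param X Samples-by-taxa matrix.
#' @param Y Samples-by-alcohols matrix.
#' @param spec A [scaling_spec()].
#' @return list(X, Y) scaled per the spec.
#' @export
o2pls_preprocess <- function(X, Y, spec = scaling_spec()) {
  stopifnot(inherits(spec, "scaling_spec"))
  if (spec$zscore_columns) {
    list(X = scale_block(X, center = TRUE, unit_variance = TRUE,
                         equal_total_ssq = FALSE),
         Y = scale_block(Y, center = TRUE, unit_variance = TRUE,
                         equal_total_ssq = FALSE))
  } else {
    list(X = scale_block(X, center = spec$center, unit_variance = FALSE,
                         equal_total_ssq = spec$equal_total_ssq),
         Y = scale_block(Y, center = spec$center,
                         unit_variance = spec$unit_variance_y,
                         equal_total_ssq = spec$equal_total_ssq))
  }
}

# fix svd sign indeterminacy: flip each (u_k, v_k) pair so the largest-|.|
# entry of u_k is positive
align_svd_signs <- function(U, V) {
  for (k in seq_len(ncol(U))) {
    i <- which.max(abs(U[, k]))
    if (U[i, k] < 0) {
      U[, k] <- -U[, k]
      V[, k] <- -V[, k]
    }
  }
  list(U = U, V = V)
}

joint_svd <- function(X, Y, n) {
  sv <- svd(crossprod(X, Y), nu = n, nv = n)
  al <- align_svd_signs(sv$u, sv$v)
  list(W = al$U, C = al$V)
}

#' Fit a two-way orthogonal PLS model
#'
#' Joint loadings are initialized from the n leading singular triplets of
#' \eqn{X^\top Y}. For each of the nx (resp. ny) orthogonal components, the
#' dominant direction of the part of X (resp. Y) that is predicted by the
#' joint scores but orthogonal to the joint loadings is extracted and the
#' block deflated; the joint parts are then recomputed on the deflated data.
#' The inner relation B is the least-squares regression of the Y joint
#' scores U on the X joint scores T.
#'
#' The fitted model satisfies, up to floating point: unit-norm loading
#' columns, \eqn{T^\top T_{orth} = 0}, \eqn{U^\top U_{orth} = 0}, and exact
#' decomposition of each block's sum of squares into joint + orthogonal +
#' residual.
#'
#' @param X Samples-by-p matrix (preprocessed; see [o2pls_preprocess()]).
#' @param Y Samples-by-q matrix.
#' @param n Number of joint components (>= 1).
#' @param nx,ny Numbers of X- and Y-side orthogonal components (>= 0).
#' @return An object of class \code{o2pls_model}: loadings \code{W} (p x n),
#'   \code{C} (q x n); scores \code{Tt}, \code{U} (N x n); orthogonal parts
#'   \code{W_orth}, \code{P_orth_x}, \code{T_orth} and \code{C_orth},
#'   \code{P_orth_y}, \code{U_orth}; inner relation \code{B} (n x n);
#'   \code{variance_explained} per block.
#' @export
o2pls_fit <- function(X, Y, n = 2, nx = 1, ny = 1) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y need the same samples", call. = FALSE)
  if (n < 1) stop("need at least one joint component", call. = FALSE)
  if (n + max(nx, ny) > min(nrow(X), ncol(X), ncol(Y))) {
    stop("n + max(nx, ny) exceeds the smallest data dimension",
         call. = FALSE)
  }
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (is.null(colnames(Y))) colnames(Y) <- paste0("y", seq_len(ncol(Y)))
  ssq_x <- sum(X^2); ssq_y <- sum(Y^2)

  js <- joint_svd(X, Y, n)
  W <- js$W; C <- js$C
  Tt <- X %*% W
  U <- Y %*% C

  W_orth <- matrix(0, ncol(X), 0); P_orth_x <- matrix(0, ncol(X), 0)
  T_orth <- matrix(0, nrow(X), 0)
  for (i in seq_len(nx)) {
    E <- X - Tt %*% t(W)                       # loading-orthogonal part
    w_o <- svd(crossprod(E, Tt), nu = 1, nv = 0)$u[, 1]
    i_mx <- which.max(abs(w_o))
    if (w_o[i_mx] < 0) w_o <- -w_o
    t_o <- X %*% w_o
    p_o <- crossprod(X, t_o) / c(crossprod(t_o))
    X <- X - t_o %*% t(p_o)
    W_orth <- cbind(W_orth, w_o)
    P_orth_x <- cbind(P_orth_x, p_o)
    T_orth <- cbind(T_orth, t_o)
    Tt <- X %*% W
  }

  C_orth <- matrix(0, ncol(Y), 0); P_orth_y <- matrix(0, ncol(Y), 0)
  U_orth <- matrix(0, nrow(Y), 0)
  for (i in seq_len(ny)) {
    Fm <- Y - U %*% t(C)
    c_o <- svd(crossprod(Fm, U), nu = 1, nv = 0)$u[, 1]
    i_mx <- which.max(abs(c_o))
    if (c_o[i_mx] < 0) c_o <- -c_o
    u_o <- Y %*% c_o
    p_o <- crossprod(Y, u_o) / c(crossprod(u_o))
    Y <- Y - u_o %*% t(p_o)
    C_orth <- cbind(C_orth, c_o)
    P_orth_y <- cbind(P_orth_y, p_o)
    U_orth <- cbind(U_orth, u_o)
    U <- Y %*% C
  }

  # joint parts recomputed on the deflated blocks
  js <- joint_svd(X, Y, n)
  W <- js$W; C <- js$C
  Tt <- X %*% W
  U <- Y %*% C
  B <- solve(crossprod(Tt), crossprod(Tt, U))

  dn <- function(M, rn, cn) {
    dimnames(M) <- list(rn, cn); M
  }
  comp <- paste0("joint", seq_len(n))
  cx <- if (nx > 0) paste0("orth_x", seq_len(nx)) else character(0)
  cy <- if (ny > 0) paste0("orth_y", seq_len(ny)) else character(0)
  joint_x <- sum((Tt %*% t(W))^2); orth_x <- sum((T_orth %*% t(P_orth_x))^2)
  joint_y <- sum((U %*% t(C))^2); orth_y <- sum((U_orth %*% t(P_orth_y))^2)
  structure(list(
    W = dn(W, colnames(X), comp), C = dn(C, colnames(Y), comp),
    Tt = dn(Tt, rownames(X), comp), U = dn(U, rownames(Y), comp),
    W_orth = dn(W_orth, colnames(X), cx),
    P_orth_x = dn(P_orth_x, colnames(X), cx),
    T_orth = dn(T_orth, rownames(X), cx),
    C_orth = dn(C_orth, colnames(Y), cy),
    P_orth_y = dn(P_orth_y, colnames(Y), cy),
    U_orth = dn(U_orth, rownames(Y), cy),
    B = B,
    variance_explained = list(
      x = c(joint = joint_x / ssq_x, orthogonal = orth_x / ssq_x,
            residual = 1 - (joint_x + orth_x) / ssq_x),
      y = c(joint = joint_y / ssq_y, orthogonal = orth_y / ssq_y,
            residual = 1 - (joint_y + orth_y) / ssq_y)
    ),
    dims = list(n = n, nx = nx, ny = ny, N = nrow(X),
                p = ncol(X), q = ncol(Y)),
    ssq = c(x = ssq_x, y = ssq_y)
  ), class = "o2pls_model")
}

#' @export
print.o2pls_model <- function(x, ...) {
  d <- x$dims
  cat(sprintf("o2pls_model: N=%d, p=%d, q=%d; %d joint, %d/%d orthogonal\n",
              d$N, d$p, d$q, d$n, d$nx, d$ny))
  ve <- x$variance_explained
  cat(sprintf("  X: joint %.1f%%, orth %.1f%%, residual %.1f%%\n",
              100 * ve$x["joint"], 100 * ve$x["orthogonal"],
              100 * ve$x["residual"]))
  cat(sprintf("  Y: joint %.1f%%, orth %.1f%%, residual %.1f%%\n",
              100 * ve$y["joint"], 100 * ve$y["orthogonal"],
              100 * ve$y["residual"]))
  invisible(x)
}

#' Permutation test for influential O2PLS variables
#'
#' Breaks the X-Y sample linkage by reshuffling the rows of Y with a seeded
#' random permutation, refits the model, and pools the permuted joint
#' loadings (per component, per block, sign-aligned to the observed loading
#' vector by the dot-product convention) into an empirical null. A variable
#' is significant when its observed joint loading falls below the
#' \eqn{\alpha/2} or above the \eqn{1 - \alpha/2} null quantile in any
#' joint component. Quantiles use the inclusive (type-7) convention.
#'
#' @param X,Y Preprocessed blocks as for [o2pls_fit()].
#' @param n,nx,ny Component numbers as for [o2pls_fit()].
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed driving the permutation stream.
#' @param keep_null Keep the pooled null loading values (memory permitting).
#' @return An object of class \code{o2pls_permutation}: \code{significant_x},
#'   \code{significant_y} (variable id sets), per-component
#'   \code{lower_q}/\code{upper_q} for both blocks, the observed loadings,
#'   \code{n_perm}, \code{alpha}, \code{seed}.
#' @export
o2pls_permutation_test <- function(X, Y, n = 2, nx = 1, ny = 1,
                                   n_perm = 1000, alpha = 0.05, seed = 1,
                                   keep_null = FALSE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  if (n_perm < 100) {
    warning("fewer than 100 permutations gives coarse quantiles",
            call. = FALSE)
  }
  fit0 <- o2pls_fit(X, Y, n, nx, ny)
  W0 <- fit0$W; C0 <- fit0$C
  null_x <- array(NA_real_, c(nrow(W0), n, n_perm))
  null_y <- array(NA_real_, c(nrow(C0), n, n_perm))
  set.seed(seed)
  Y <- as.matrix(Y)
  for (b in seq_len(n_perm)) {
    fit_b <- o2pls_fit(X, Y[sample(nrow(Y)), , drop = FALSE], n, nx, ny)
    Wb <- fit_b$W; Cb <- fit_b$C
    for (k in seq_len(n)) {                 # align sign to observed loadings
      if (sum(Wb[, k] * W0[, k]) < 0) Wb[, k] <- -Wb[, k]
      if (sum(Cb[, k] * C0[, k]) < 0) Cb[, k] <- -Cb[, k]
    }
    null_x[, , b] <- Wb
    null_y[, , b] <- Cb
  }
  qs <- function(null, k) {
    stats::quantile(null[, k, ], probs = c(alpha / 2, 1 - alpha / 2),
                    names = FALSE, type = 7)
  }
  lower_x <- upper_x <- lower_y <- upper_y <- numeric(n)
  sig_x <- rep(FALSE, nrow(W0)); sig_y <- rep(FALSE, nrow(C0))
  for (k in seq_len(n)) {
    qx <- qs(null_x, k); qy <- qs(null_y, k)
    lower_x[k] <- qx[1]; upper_x[k] <- qx[2]
    lower_y[k] <- qy[1]; upper_y[k] <- qy[2]
    sig_x <- sig_x | W0[, k] < qx[1] | W0[, k] > qx[2]
    sig_y <- sig_y | C0[, k] < qy[1] | C0[, k] > qy[2]
  }
  structure(list(
    significant_x = rownames(W0)[sig_x],
    significant_y = rownames(C0)[sig_y],
    lower_q = list(x = lower_x, y = lower_y),
    upper_q = list(x = upper_x, y = upper_y),
    loadings_x = W0, loadings_y = C0,
    null_loadings = if (keep_null) list(x = null_x, y = null_y),
    n_perm = n_perm, alpha = alpha, seed = seed,
    dims = fit0$dims
  ), class = "o2pls_permutation")
}

#' @export
print.o2pls_permutation <- function(x, ...) {
  cat(sprintf(
    "o2pls_permutation: %d permutations, alpha=%.3g; %d/%d X and %d/%d Y %s\n",
    x$n_perm, x$alpha, length(x$significant_x), x$dims$p,
    length(x$significant_y), x$dims$q, "variables significant"))
  invisible(x)
}

#' Serialize an O2PLS model (and optional permutation result) to JSON
#'
#' @param model An \code{o2pls_model}.
#' @param path Output JSON path.
#' @param perm Optional \code{o2pls_permutation} to embed.
#' @return \code{path}, invisibly.
#' @export
write_o2pls_json <- function(model, path, perm = NULL) {
  stopifnot(inherits(model, "o2pls_model"))
  obj <- list(
    dims = model$dims,
    loadings_x = model$W, loadings_y = model$C,
    scores_x = model$Tt, scores_y = model$U,
    inner_relation = model$B,
    variance_explained = model$variance_explained
  )
  if (!is.null(perm)) {
    obj$permutation <- list(
      n_perm = perm$n_perm, alpha = perm$alpha, seed = perm$seed,
      significant_x = perm$significant_x,
      significant_y = perm$significant_y,
      lower_q = perm$lower_q, upper_q = perm$upper_q
    )
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}
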