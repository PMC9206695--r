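rand_pair <- function(N, p, q, seed) {
  set.seed(seed)
  list(X = matrix(rnorm(N * p), N, p), Y = matrix(rnorm(N * q), N, q))
}

test_that("preprocessing matches the declared scaling modes", {
  d <- rand_pair(10, 6, 4, 1)
  b <- o2pls_preprocess(d$X, d$Y)
  expect_equal(colSums(b$X), rep(0, 6), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(colSums(b$Y), rep(0, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(b$X^2), 1, tolerance = 1e-12)  # Frobenius norm 1
  expect_equal(sum(b$Y^2), 1, tolerance = 1e-12)
  # Y columns unit variance before the total-SSQ rescale: constant ratio
  sds <- apply(b$Y, 2, sd)
  expect_equal(sds / sds[1], rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  z <- o2pls_preprocess(d$X, d$Y,
                        scaling_spec(unit_variance_y = FALSE,
                                     equal_total_ssq = FALSE,
                                     zscore_columns = TRUE))
  expect_equal(apply(z$X, 2, sd), rep(1, 6), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(z$Y, 2, mean), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  Xc <- d$X; Xc[, 2] <- 3
  expect_error(o2pls_preprocess(d$Y, Xc), "zero-variance")
  expect_error(scaling_spec(zscore_columns = TRUE), "alternative mode")
})

test_that("self-integration gives identical loadings, scores and unit B", {
  d <- rand_pair(8, 5, 5, 2)
  X <- scale(d$X, scale = FALSE)
  fit <- o2pls_fit(X, X, n = 1, nx = 0, ny = 0)
  expect_equal(fit$W, fit$C, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(fit$Tt, fit$U, tolerance = 1e-10, ignore_attr = TRUE)
  expect_equal(as.numeric(fit$B), 1, tolerance = 1e-10)
})

test_that("the nx=ny=0 reduction matches the eigendecomposition oracle", {
  for (s in 1:25) {
    d <- rand_pair(6, 8, 5, 100 + s)
    fit <- o2pls_fit(d$X, d$Y, n = 2, nx = 0, ny = 0)
    or <- plssvd_oracle(d$X, d$Y, 2)
    expect_equal(align_columns(or$W, fit$W), fit$W, tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(align_columns(or$C, fit$C), fit$C, tolerance = 1e-8,
                 ignore_attr = TRUE)
  }
})

test_that("single-response, single-component X loading is along X'y", {
  d <- rand_pair(9, 6, 1, 3)
  fit <- o2pls_fit(d$X, d$Y, n = 1, nx = 0, ny = 0)
  v <- crossprod(d$X, d$Y)[, 1]
  v <- v / sqrt(sum(v^2))
  expect_equal(abs(sum(v * fit$W[, 1])), 1, tolerance = 1e-10)
})

test_that("orthogonality and norm conservation hold on random fits", {
  set.seed(77)
  for (i in 1:20) {
    N <- sample(6:12, 1)
    p <- sample(5:12, 1)
    q <- sample(4:8, 1)
    n <- sample(1:2, 1)
    nx <- sample(0:2, 1)
    ny <- sample(0:2, 1)
    if (n + max(nx, ny) > min(N, p, q)) next
    d <- rand_pair(N, p, q, 500 + i)
    b <- o2pls_preprocess(d$X, d$Y)
    fit <- o2pls_fit(b$X, b$Y, n, nx, ny)
    expect_equal(crossprod(fit$W), diag(n), tolerance = 1e-8,
                 ignore_attr = TRUE)
    expect_equal(crossprod(fit$C), diag(n), tolerance = 1e-8,
                 ignore_attr = TRUE)
    if (nx > 0) {
      expect_lt(max(abs(crossprod(fit$Tt, fit$T_orth))), 1e-8)
    }
    if (ny > 0) {
      expect_lt(max(abs(crossprod(fit$U, fit$U_orth))), 1e-8)
    }
    ve <- fit$variance_explained
    expect_equal(sum(ve$x), 1, tolerance = 1e-6)
    expect_equal(sum(ve$y), 1, tolerance = 1e-6)
    expect_true(all(ve$x >= -1e-9) && all(ve$y >= -1e-9))
  }
})

test_that("a planted rank-1 signal couples the joint scores", {
  set.seed(21)
  t_true <- rnorm(30)
  w <- rnorm(12); w <- w / sqrt(sum(w^2))
  c_ <- rnorm(6); c_ <- c_ / sqrt(sum(c_^2))
  X <- t_true %*% t(w) + 0.01 * matrix(rnorm(30 * 12), 30, 12)
  Y <- t_true %*% t(c_) + 0.01 * matrix(rnorm(30 * 6), 30, 6)
  fit <- o2pls_fit(scale(X, scale = FALSE), scale(Y, scale = FALSE),
                   n = 1, nx = 1, ny = 1)
  expect_gt(abs(cor(fit$Tt[, 1], fit$U[, 1])), 0.99)
})

test_that("sign flips leave reconstruction and selection invariant", {
  d <- rand_pair(10, 7, 5, 5)
  b <- o2pls_preprocess(d$X, d$Y)
  fit <- o2pls_fit(b$X, b$Y, n = 2, nx = 1, ny = 1)
  recon <- fit$Tt %*% t(fit$W)
  flip <- fit
  flip$W[, 1] <- -flip$W[, 1]
  flip$Tt[, 1] <- -flip$Tt[, 1]
  expect_equal(flip$Tt %*% t(flip$W), recon, tolerance = 1e-12)
})

test_that("the permutation test is deterministic and flags planted producers", {
  dat <- simulate_dataset(sim_config(effect_size = 1, noise_sd = 0.1,
                                     seed = 5))
  X <- t(to_relative(dat$abundance)$abund)
  Y <- t(dat$ha$replicate_values)
  Y[is.na(Y)] <- 0
  b <- o2pls_preprocess(X, Y)
  p1 <- o2pls_permutation_test(b$X, b$Y, n = 5, nx = 1, ny = 1,
                               n_perm = 200, alpha = 0.05, seed = 9)
  p2 <- o2pls_permutation_test(b$X, b$Y, n = 5, nx = 1, ny = 1,
                               n_perm = 200, alpha = 0.05, seed = 9)
  expect_identical(p1$significant_x, p2$significant_x)
  expect_identical(p1$significant_y, p2$significant_y)
  expect_true(all(dat$truth$producer_ids %in% p1$significant_x))
  expect_true(all(p1$lower_q$x <= p1$upper_q$x))
})

test_that("component counts and permutation settings are validated", {
  d <- rand_pair(6, 5, 4, 6)
  expect_error(o2pls_fit(d$X, d$Y, n = 0), "joint component")
  expect_error(o2pls_fit(d$X, d$Y, n = 4, nx = 2), "dimension")
  expect_error(o2pls_permutation_test(d$X, d$Y, alpha = 1.5), "alpha")
  expect_warning(o2pls_permutation_test(d$X, d$Y, n = 1, nx = 0, ny = 0,
                                        n_perm = 50, seed = 1),
                 "100 permutations")
})
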