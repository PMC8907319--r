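test_that("fold assignment is balanced, exhaustive and seed-reproducible", {
  f <- tenfold_split(10, 10, seed = 1)
  expect_identical(sort(tabulate(f$fold_of, 10)), rep(1L, 10))
  f118 <- tenfold_split(118, 10, seed = 9)
  sizes <- sort(tabulate(f118$fold_of, 10))
  expect_identical(sizes, c(11L, 11L, rep(12L, 8)))
  expect_identical(tenfold_split(118, 10, seed = 9)$fold_of, f118$fold_of)
  expect_false(identical(tenfold_split(118, 10, seed = 10)$fold_of,
                         f118$fold_of))
  expect_error(tenfold_split(5, 10), "n_samples >= n_folds")
})

test_that("PLS recovers an exact rank-1 relation with one latent variable", {
  set.seed(21)
  x1 <- rnorm(30)
  X <- cbind(x1, matrix(0, 30, 3))
  y <- 2 * x1
  m <- fit_pls(X, y, n_latent = 1)
  expect_lt(max(abs(predict(m, X) - y)), 1e-8)
})

test_that("full-component PLS equals least squares on full-rank data", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(20 * 5), 20)
    y <- rnorm(20)
    m <- fit_pls(X, y, n_latent = 5)
    ols <- cbind(1, X) %*% solve(crossprod(cbind(1, X)),
                                 crossprod(cbind(1, X), y))
    expect_lt(max(abs(predict(m, X) - drop(ols))), 1e-6)
  }
  expect_error(fit_pls(matrix(rnorm(20), 10), rep(1, 10), 1),
               "zero variance")
  expect_error(fit_pls(matrix(rnorm(20), 10), rnorm(10), 5), "exceeds")
})

test_that("PLS predictions scale with the response (affine equivariance)", {
  set.seed(31)
  X <- matrix(rnorm(25 * 6), 25)
  y <- rnorm(25)
  Xn <- matrix(rnorm(10 * 6), 10)
  p1 <- predict(fit_pls(X, y, 3), Xn)
  p3 <- predict(fit_pls(X, 3 * y, 3), Xn)
  expect_equal(p3, 3 * p1, tolerance = 1e-10)
  m <- fit_pls(X, y, 3)
  expect_equal(predict(m, X), m$fitted)
  expect_error(predict(m, Xn[, 1:4]), "columns")
})

test_that("latent-count selection recovers a known generative rank", {
  hits <- 0
  for (seed in 1:10) {
    set.seed(seed)
    n <- 60
    t1 <- rnorm(n); t2 <- rnorm(n)
    X <- cbind(outer(t1, rnorm(8)), outer(t2, rnorm(8))) +
      matrix(rnorm(n * 16, sd = 0.01), n)
    y <- t1 - 0.5 * t2 + rnorm(n, sd = 0.02)
    folds <- tenfold_split(n, 10, seed)
    a <- choose_n_latent(X, y, folds, max_latent = 8)
    if (a == 2L) hits <- hits + 1
  }
  expect_gte(hits, 8)
  # single candidate returns it; pure noise still returns a value in range
  set.seed(99)
  X <- matrix(rnorm(40 * 5), 40); y <- rnorm(40)
  folds <- tenfold_split(40, 10, 2)
  expect_identical(choose_n_latent(X, y, folds, max_latent = 1), 1L)
  a <- choose_n_latent(X, y, folds, max_latent = 5)
  expect_true(a >= 1 && a <= 5)
})

test_that("SVR fits a linear relation to within its tube", {
  set.seed(41)
  x <- matrix(rnorm(40), 40)
  y <- drop(3 * x + 1)
  m <- fit_svr(x, y, C = 1, epsilon = 0.01)
  expect_lt(rmse(y, predict(m, x)), 0.01 * sd(y) + 1e-3)
  # constant y: constant predictions inside the tube
  mc <- fit_svr(x, rep(2.5, 40), C = 1, epsilon = 0.1)
  expect_true(all(abs(predict(mc, x) - 2.5) < 0.1))
})

test_that("SVR agrees with an independent QP solution of its dual", {
  for (seed in 1:5) {
    set.seed(seed)
    X <- matrix(rnorm(10 * 3), 10)
    y <- rnorm(10)
    m <- fit_svr(X, y, C = 1, epsilon = 0.1, tolerance = 1e-8)
    p_qp <- svr_qp_predict(X, y, C = 1, eps = 0.1, Xnew = X)
    expect_lt(max(abs(predict(m, X) - p_qp)), 1e-4)
  }
})

test_that("SVR satisfies KKT: strictly-in-tube points carry no dual weight", {
  set.seed(55)
  X <- matrix(rnorm(30 * 3), 30)
  y <- drop(X %*% c(1, -2, 0.5)) + rnorm(30, sd = 0.3)
  m <- fit_svr(X, y, C = 1, epsilon = 0.2, tolerance = 1e-8)
  res_std <- (predict(m, X) - y) / m$ysd     # residuals on solver scale
  sv_idx <- m$svm$index
  non_sv <- setdiff(seq_len(30), sv_idx)
  expect_true(all(abs(res_std[non_sv]) <= 0.2 + 1e-6))
  expect_true(all(abs(m$svm$coefs) <= 1 + 1e-8))
})

test_that("pooled RMSECV matches its definition and reference path", {
  set.seed(61)
  X <- matrix(rnorm(50 * 8), 50)
  y <- drop(X %*% rnorm(8)) + rnorm(50, sd = 0.1)
  folds <- tenfold_split(50, 10, 3)
  # compiled path equals the R reference and the per-fold generic route
  r_cpp <- cv_rmse(pls_spec(4), X, y, folds)
  r_ref <- sqrt(mean(nirselect:::pls_cv_resid(X, y, folds$fold_of,
                                              10, 4)^2))
  expect_equal(r_cpp, r_ref, tolerance = 1e-12)
  resid <- numeric(50)
  for (k in 1:10) {
    te <- folds$fold_of == k
    m <- fit_pls(X[!te, ], y[!te], 4)
    resid[te] <- predict(m, X[te, , drop = FALSE]) - y[te]
  }
  expect_equal(r_cpp, sqrt(mean(resid^2)), tolerance = 1e-10)
  expect_gte(r_cpp, 0)
  # zero-noise rank-1 data cross-validates to ~0 with one latent variable
  x1 <- X[, 1]
  X1 <- cbind(x1, 0.5 * x1, -2 * x1)
  expect_lt(cv_rmse(pls_spec(1), X1, x1 * 3, folds), 1e-6)
})

test_that("RMSECV of a mean-only model approaches sd(y)", {
  set.seed(71)
  n <- 400
  X <- matrix(0.001 * rnorm(n), n)  # near-constant predictor
  y <- rnorm(n)
  folds <- tenfold_split(n, 10, 5)
  expect_equal(cv_rmse(pls_spec(1), X, y, folds), sd(y),
               tolerance = 0.05)
})

test_that("RMSECV is invariant under consistent sample permutation", {
  set.seed(81)
  X <- matrix(rnorm(40 * 6), 40)
  y <- rnorm(40)
  folds <- tenfold_split(40, 10, 7)
  perm <- sample(40)
  folds_p <- folds
  folds_p$fold_of <- folds$fold_of[perm]
  expect_equal(cv_rmse(pls_spec(3), X[perm, ], y[perm], folds_p),
               cv_rmse(pls_spec(3), X, y, folds),
               tolerance = 1e-12)
})
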