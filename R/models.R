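# Evaluate expr with a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a stream seed from a base seed and an index; stays below 2^31.
derive_seed <- function(base_seed, index) {
  as.integer((as.double(base_seed) * 48271 + as.double(index) * 16807) %%
               2147483629)
}

#' Random balanced k-fold assignment
#'
#' Assigns each sample to one of `n_folds` folds whose sizes differ by at
#' most one, so that in a full cross-validation rotation every data point
#' is used for training in all but one fold and for testing exactly once.
#' With 118 samples and 10 folds this gives eight folds of 12 and two of
#' 11. Reproducible for a fixed seed; the caller's RNG state is untouched.
#'
#' @param n_samples number of samples.
#' @param n_folds number of folds (default 10).
#' @param seed integer seed.
#' @return Object of class `fold_assignment`: list with `n_samples`,
#'   `n_folds`, `fold_of` (integer vector of fold ids in 1..n_folds),
#'   `seed`.
#' @export
tenfold_split <- function(n_samples, n_folds = 10L, seed = 1L) {
  n_samples <- as.integer(n_samples); n_folds <- as.integer(n_folds)
  if (n_folds < 2L || n_samples < n_folds)
    stop("need n_samples >= n_folds >= 2", call. = FALSE)
  fold_of <- with_seed(seed,
    sample(rep(seq_len(n_folds), length.out = n_samples)))
  structure(list(n_samples = n_samples, n_folds = n_folds,
                 fold_of = fold_of, seed = as.integer(seed)),
            class = "fold_assignment")
}

#' PLS model specification
#' @param n_latent number of latent variables to extract.
#' @return A model spec usable with [fit_model()] and [cv_rmse()].
#' @export
pls_spec <- function(n_latent) {
  stopifnot(n_latent >= 1)
  structure(list(kind = "pls", n_latent = as.integer(n_latent)),
            class = "model_spec")
}

#' Linear epsilon-SVR model specification
#'
#' Kernel is fixed linear; `C` defaults to 1 (the library default, used
#' without further tuning) and `epsilon` is the insensitive-tube half-width
#' on the standardized-response scale.
#'
#' @param C penalty parameter, > 0.
#' @param epsilon tube half-width, >= 0.
#' @return A model spec usable with [fit_model()] and [cv_rmse()].
#' @export
svr_spec <- function(C = 1, epsilon = 0.1) {
  stopifnot(C > 0, epsilon >= 0)
  structure(list(kind = "svr", C = C, epsilon = epsilon),
            class = "model_spec")
}

#' Fit a calibration model from a spec
#' @param spec a [pls_spec()] or [svr_spec()].
#' @param X numeric matrix of predictors (rows = samples).
#' @param y numeric response vector.
#' @return A fitted model with a [predict][predict.nirselect_model] method.
#' @export
fit_model <- function(spec, X, y) {
  stopifnot(inherits(spec, "model_spec"))
  switch(spec$kind,
         pls = fit_pls(X, y, n_latent = spec$n_latent),
         svr = fit_svr(X, y, C = spec$C, epsilon = spec$epsilon),
         stop("unknown model kind: ", spec$kind))
}

# NIPALS PLS1: deflation-based extraction of `ncomp` latent variables from
# column-centered X against centered y. Returns regression coefficients for
# every truncation 1..ncomp (one column of B per latent-variable count).
nipals_pls <- function(X, y, ncomp) {
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n == length(y), n >= 2)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in predictors or response", call. = FALSE)
  if (stats::var(y) == 0)
    stop("response has zero variance", call. = FALSE)
  rank_cap <- min(n - 1L, p)
  if (ncomp > rank_cap)
    stop("n_latent (", ncomp, ") exceeds min(n_samples-1, n_vars) = ",
         rank_cap, call. = FALSE)
  xbar <- colMeans(X); ybar <- mean(y)
  E <- sweep(X, 2L, xbar); f <- y - ybar
  W <- P <- matrix(0, p, ncomp)
  Q <- numeric(ncomp)
  a_done <- 0L
  for (a in seq_len(ncomp)) {
    w <- crossprod(E, f)                      # p x 1 covariance direction
    nw <- sqrt(sum(w^2))
    if (nw < 1e-14) break                     # X exhausted: stop early
    w <- w / nw
    t <- E %*% w
    tt <- sum(t^2)
    if (tt < 1e-14) break
    p_a <- crossprod(E, t) / tt
    q_a <- sum(f * t) / tt
    E <- E - t %*% t(p_a)
    f <- f - q_a * t
    W[, a] <- w; P[, a] <- p_a; Q[a] <- q_a
    a_done <- a
  }
  if (a_done == 0L) stop("PLS failed: predictors are constant", call. = FALSE)
  W <- W[, seq_len(a_done), drop = FALSE]
  P <- P[, seq_len(a_done), drop = FALSE]
  Q <- Q[seq_len(a_done)]
  # B_a = W_a (P_a' W_a)^-1 q_a for each truncation a
  B <- matrix(0, p, a_done)
  for (a in seq_len(a_done)) {
    B[, a] <- W[, 1:a, drop = FALSE] %*%
      solve(crossprod(P[, 1:a, drop = FALSE], W[, 1:a, drop = FALSE]),
            Q[1:a])
  }
  list(xbar = xbar, ybar = ybar, B = B, ncomp = a_done)
}

#' Fit a PLS calibration model
#'
#' Single-response partial least squares by NIPALS deflation on
#' column-centered data. No unit-variance scaling of X is applied (SNV
#' pretreatment already puts spectra on a common scale). Predictions are
#' affine in X.
#'
#' @param X numeric matrix (rows = samples).
#' @param y numeric response (content, %).
#' @param n_latent number of latent variables,
#'   `1 <= n_latent <= min(nrow(X)-1, ncol(X))`.
#' @return Object of class `nirselect_model` (kind `"pls"`).
#' @export
fit_pls <- function(X, y, n_latent) {
  fit <- nipals_pls(X, y, n_latent)
  m <- structure(list(kind = "pls", n_latent = fit$ncomp,
                      requested_latent = as.integer(n_latent),
                      xbar = fit$xbar, ybar = fit$ybar,
                      coef = fit$B[, fit$ncomp],
                      n_vars = ncol(as.matrix(X))),
                 class = "nirselect_model")
  m$fitted <- predict(m, X)
  m
}

#' Fit a linear epsilon-SVR calibration model
#'
#' Linear epsilon-insensitive support vector regression, solved by
#' \code{e1071::svm} on standardized columns (zero-variance columns are
#' dropped from the fit); `epsilon` acts on the standardized-response
#' scale, predictions are returned in original units.
#'
#' @inheritParams fit_pls
#' @param C penalty parameter (> 0); default 1.
#' @param epsilon insensitive-tube half-width (>= 0) on the standardized-y
#'   scale; default 0.1.
#' @param tolerance termination tolerance of the underlying solver.
#' @return Object of class `nirselect_model` (kind `"svr"`).
#' @export
fit_svr <- function(X, y, C = 1, epsilon = 0.1, tolerance = 0.001) {
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), nrow(X) >= 2, C > 0, epsilon >= 0)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in predictors or response", call. = FALSE)
  xbar <- colMeans(X)
  xsd <- apply(X, 2L, stats::sd)
  keep <- which(xsd > 0)
  ybar <- mean(y); ysd <- stats::sd(y)
  if (ysd == 0) {
    # degenerate response: constant prediction sits inside any tube
    m <- structure(list(kind = "svr", constant = ybar, n_vars = ncol(X)),
                   class = "nirselect_model")
    m$fitted <- rep(ybar, nrow(X))
    return(m)
  }
  Z <- sweep(sweep(X[, keep, drop = FALSE], 2L, xbar[keep]), 2L,
             xsd[keep], "/")
  ys <- (y - ybar) / ysd
  fit <- e1071::svm(x = Z, y = ys, type = "eps-regression",
                    kernel = "linear", cost = C, epsilon = epsilon,
                    scale = FALSE, tolerance = tolerance)
  m <- structure(list(kind = "svr", svm = fit, keep = keep,
                      xbar = xbar, xsd = xsd, ybar = ybar, ysd = ysd,
                      C = C, epsilon = epsilon, n_vars = ncol(X)),
                 class = "nirselect_model")
  m$fitted <- predict(m, X)
  m
}

#' Predict from a fitted calibration model
#' @param object a `nirselect_model` from [fit_pls()] or [fit_svr()].
#' @param newdata numeric matrix with the training number of columns.
#' @param ... unused.
#' @return numeric vector of predictions in response units (%).
#' @export
predict.nirselect_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (ncol(X) != object$n_vars)
    stop("newdata has ", ncol(X), " columns; model expects ",
         object$n_vars, call. = FALSE)
  if (object$kind == "pls") {
    drop(sweep(X, 2L, object$xbar) %*% object$coef) + object$ybar
  } else if (!is.null(object$constant)) {
    rep(object$constant, nrow(X))
  } else {
    Z <- sweep(sweep(X[, object$keep, drop = FALSE], 2L,
                     object$xbar[object$keep]), 2L,
               object$xsd[object$keep], "/")
    as.numeric(stats::predict(object$svm, Z)) * object$ysd + object$ybar
  }
}

#' @export
print.nirselect_model <- function(x, ...) {
  if (x$kind == "pls")
    cat(sprintf("PLS calibration model: %d latent variables, %d variables\n",
                x$n_latent, x$n_vars))
  else
    cat(sprintf("linear eps-SVR calibration model: C=%g, epsilon=%g, %d variables\n",
                if (is.null(x$C)) NA else x$C,
                if (is.null(x$epsilon)) NA else x$epsilon, x$n_vars))
  invisible(x)
}

# Lean PLS cross-validation path: one NIPALS pass per fold, final-truncation
# coefficients only, no model objects. Numerically identical to fitting
# fit_pls() per fold and predicting (asserted in the test suite).
pls_cv_resid <- function(X, y, fold_of, n_folds, ncomp) {
  n <- nrow(X); p <- ncol(X)
  resid <- numeric(n)
  for (k in seq_len(n_folds)) {
    test <- fold_of == k
    Xtr <- X[!test, , drop = FALSE]
    ytr <- y[!test]
    ntr <- nrow(Xtr)
    xbar <- .colMeans(Xtr, ntr, p)
    ybar <- mean(ytr)
    E <- Xtr - rep(xbar, each = ntr)
    f <- ytr - ybar
    a_max <- min(ncomp, ntr - 1L, p)
    W <- P <- matrix(0, p, a_max)
    Q <- numeric(a_max)
    ad <- 0L
    for (a in seq_len(a_max)) {
      w <- crossprod(E, f)
      nw <- sqrt(sum(w * w))
      if (nw < 1e-14) break
      w <- w / nw
      tt <- E %*% w
      t2 <- sum(tt * tt)
      if (t2 < 1e-14) break
      p_a <- crossprod(E, tt) / t2
      q_a <- sum(f * tt) / t2
      E <- E - tcrossprod(tt, p_a)
      f <- f - q_a * tt
      W[, a] <- w; P[, a] <- p_a; Q[a] <- q_a
      ad <- a
    }
    pred <- if (ad == 0L) ybar else {
      B <- W[, 1:ad, drop = FALSE] %*%
        solve(crossprod(P[, 1:ad, drop = FALSE], W[, 1:ad, drop = FALSE]),
              Q[1:ad])
      X[test, , drop = FALSE] %*% B + (ybar - sum(xbar * B))
    }
    resid[test] <- pred - y[test]
  }
  resid
}

#' Cross-validated RMSE
#'
#' Root mean square error of cross-validation (RMSECV): fits the model on
#' each fold's complement, predicts the held-out fold, pools all n
#' out-of-fold residuals, and returns the root mean square. This pooled
#' definition equals RMSEP applied to the out-of-fold predictions and is
#' deterministic given the fold assignment. Used as the BPSO fitness.
#'
#' @param spec a [pls_spec()] or [svr_spec()].
#' @param X predictor matrix.
#' @param y response vector.
#' @param folds a [tenfold_split()] assignment for `nrow(X)` samples.
#' @return non-negative number.
#' @export
cv_rmse <- function(spec, X, y, folds) {
  stopifnot(inherits(folds, "fold_assignment"))
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == folds$n_samples, length(y) == folds$n_samples)
  if (spec$kind == "pls") {
    resid <- pls_cv_resid_cpp(X, y, as.integer(folds$fold_of),
                              folds$n_folds, spec$n_latent)
  } else {
    resid <- numeric(folds$n_samples)
    for (k in seq_len(folds$n_folds)) {
      test <- folds$fold_of == k
      m <- fit_model(spec, X[!test, , drop = FALSE], y[!test])
      resid[test] <- predict(m, X[test, , drop = FALSE]) - y[test]
    }
  }
  sqrt(mean(resid^2))
}

#' Choose the PLS latent-variable count by cross-validation
#'
#' Evaluates RMSECV for every latent-variable count from 1 to `max_latent`
#' (capped by the smallest training-fold rank bound) over the given folds
#' and returns the minimizer; ties break toward the smaller count. All
#' truncations are obtained from a single NIPALS pass per fold.
#'
#' @param X predictor matrix.
#' @param y response vector.
#' @param folds a [tenfold_split()] assignment.
#' @param max_latent largest count to consider (default 15).
#' @return integer in `[1, max_latent]`.
#' @export
choose_n_latent <- function(X, y, folds, max_latent = 15L) {
  stopifnot(inherits(folds, "fold_assignment"), max_latent >= 1)
  X <- as.matrix(X); y <- as.numeric(y)
  amax <- min(as.integer(max_latent),
              folds$n_samples - max(tabulate(folds$fold_of, folds$n_folds)) - 1L,
              ncol(X))
  amax <- max(amax, 1L)
  resid <- pls_cv_resid_all_cpp(X, y, as.integer(folds$fold_of),
                                folds$n_folds, amax)
  sse <- colSums(resid^2)
  which.min(sse)  # first minimum = smallest n_latent on ties
}
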