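# Independent oracles and small fixture builders used across the suite.

# Naive elementwise-loop recomputations of the evaluation metrics.
rmse_naive <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + (yhat[i] - y[i])^2
  sqrt(s / length(y))
}

bias_naive <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + (yhat[i] - y[i])
  s / length(y)
}

sep_naive <- function(y, yhat) {
  e <- numeric(length(y))
  for (i in seq_along(y)) e[i] <- yhat[i] - y[i]
  m <- sum(e) / length(e)
  s <- 0
  for (i in seq_along(e)) s <- s + (e[i] - m)^2
  sqrt(s / (length(e) - 1))
}

pearson_naive <- function(y, yhat) {
  n <- length(y)
  my <- sum(y) / n; mh <- sum(yhat) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (y[i] - my) * (yhat[i] - mh)
    sxx <- sxx + (y[i] - my)^2
    syy <- syy + (yhat[i] - mh)^2
  }
  sxy / sqrt(sxx * syy)
}

# Linear epsilon-SVR solved from its dual QP with kernlab::ipop, on the
# same standardization fit_svr uses internally. Independent of e1071.
svr_qp_predict <- function(X, y, C, eps, Xnew) {
  xbar <- colMeans(X); xsd <- apply(X, 2, sd)
  Z <- sweep(sweep(X, 2, xbar), 2, xsd, "/")
  ybar <- mean(y); ysd <- sd(y); ys <- (y - ybar) / ysd
  n <- nrow(Z)
  K <- tcrossprod(Z)
  H <- rbind(cbind(K, -K), cbind(-K, K)) + diag(1e-10, 2 * n)
  cc <- c(eps - ys, eps + ys)
  A <- matrix(c(rep(1, n), rep(-1, n)), 1)
  sv <- kernlab::ipop(cc, H, A, b = 0, l = rep(0, 2 * n),
                      u = rep(C, 2 * n), r = 0, sigf = 12, maxiter = 200)
  al <- kernlab::primal(sv)[1:n] - kernlab::primal(sv)[(n + 1):(2 * n)]
  w <- crossprod(Z, al)
  fx <- K %*% al
  idx <- which(abs(al) > 1e-6 & abs(al) < C - 1e-6)
  b <- if (length(idx)) mean(ys[idx] - fx[idx] - sign(al[idx]) * eps)
       else mean(ys - fx)
  Zn <- sweep(sweep(Xnew, 2, xbar), 2, xsd, "/")
  drop(Zn %*% w + b) * ysd + ybar
}

# Random valid spectra_set on a descending grid.
random_spectra <- function(n = 4, p = 7, seed = 1) {
  set.seed(seed)
  spectra_set(matrix(rnorm(n * p), n),
              wavenumbers = seq(9000, 5000, length.out = p))
}

# One-component configuration with unambiguous planted segments: no
# background, no scatter, bands only.
single_band_config <- function(n_vars = 210, n_samples = 60,
                               noise_sd = 0.002, seed = 1) {
  comp <- component_spec("moisture", c(3.76, 6.29),
                         list(band_spec(7000, 50, 0.020),
                              band_spec(8040, 50, 0.016)))
  sim_config(n_samples = n_samples, grid = c(10000, 4000, n_vars),
             components = list(comp), scatter_gain_range = c(1, 1),
             scatter_offset_range = c(0, 0), baseline_amplitude = 0,
             noise_sd = noise_sd, background = NULL, seed = seed)
}
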