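#' Root mean square error
#'
#' `sqrt(mean((yhat - y)^2))` — the 1/n denominator, as used for RMSEC
#' (calibration set) and RMSEP (prediction set).
#'
#' @param y reference values.
#' @param yhat predicted values, same length.
#' @return non-negative number.
#' @export
rmse <- function(y, yhat) {
  check_pair(y, yhat)
  sqrt(mean((yhat - y)^2))
}

#' Mean signed prediction error
#'
#' `mean(yhat - y)`, predicted minus reference. The sign convention is
#' fixed (not configurable) so reports are comparable: a negative bias
#' means the model under-predicts on average.
#'
#' @inheritParams rmse
#' @return real number.
#' @export
bias <- function(y, yhat) {
  check_pair(y, yhat)
  mean(yhat - y)
}

#' Bias-corrected standard error of prediction (SEP)
#'
#' Standard deviation of the prediction residuals around their mean, with
#' the n-1 denominator: `sqrt(sum((e - mean(e))^2) / (n - 1))` for
#' `e = yhat - y`. Together with [rmse()] and [bias()] it satisfies the
#' exact identity `RMSEP^2 = SEP^2 * (n-1)/n + Bias^2`.
#'
#' @inheritParams rmse
#' @return non-negative number.
#' @export
sep <- function(y, yhat) {
  check_pair(y, yhat)
  if (length(y) < 2L) stop("SEP needs at least 2 values", call. = FALSE)
  e <- yhat - y
  sqrt(sum((e - mean(e))^2) / (length(e) - 1))
}

#' Pearson correlation between reference and predicted values
#'
#' The correlation coefficients Rc (calibration) and Rp (prediction) are
#' plain product-moment correlations between measured and predicted
#' content.
#'
#' @inheritParams rmse
#' @return number in `[-1, 1]`.
#' @export
pearson_r <- function(y, yhat) {
  check_pair(y, yhat)
  if (length(y) < 2L || stats::sd(y) == 0 || stats::sd(yhat) == 0)
    stop("correlation undefined: constant vector", call. = FALSE)
  stats::cor(y, yhat)
}

check_pair <- function(y, yhat) {
  if (length(y) != length(yhat))
    stop("y and yhat must have equal length", call. = FALSE)
  if (length(y) == 0L) stop("empty vectors", call. = FALSE)
  invisible(NULL)
}

#' Six-figure model evaluation report
#'
#' Computes the standard chemometric report for one fitted model on one
#' calibration/prediction split: Rc and RMSEC from predictions on the
#' calibration set, and Rp, RMSEP, SEP and Bias from predictions on the
#' prediction set. All error figures are in response units (%). If a
#' correlation is undefined (constant predictions, e.g. a mean-only
#' model), that field carries `NA` and the error figures are still
#' reported.
#'
#' @param model a fitted model with a `predict` method.
#' @param X_cal,y_cal calibration predictors and reference values (the
#'   data the model was trained on).
#' @param X_pred,y_pred prediction-set predictors and reference values.
#' @return Object of class `evaluation_report`: list with `Rc`, `RMSEC`,
#'   `Rp`, `RMSEP`, `SEP`, `Bias`, `n_cal`, `n_pred`.
#' @export
evaluate_model <- function(model, X_cal, y_cal, X_pred, y_pred) {
  yc <- predict(model, X_cal)
  yp <- predict(model, X_pred)
  safe_r <- function(a, b) tryCatch(pearson_r(a, b),
                                    error = function(e) NA_real_)
  structure(list(Rc = safe_r(y_cal, yc),
                 RMSEC = rmse(y_cal, yc),
                 Rp = safe_r(y_pred, yp),
                 RMSEP = rmse(y_pred, yp),
                 SEP = sep(y_pred, yp),
                 Bias = bias(y_pred, yp),
                 n_cal = length(y_cal), n_pred = length(y_pred),
                 predicted = yp, actual = y_pred),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, digits = 4, ...) {
  cat(sprintf("evaluation_report (n_cal=%d, n_pred=%d)\n", x$n_cal, x$n_pred))
  v <- unlist(x[c("Rc", "RMSEC", "Rp", "RMSEP", "SEP", "Bias")])
  print(round(v, digits))
  invisible(x)
}

#' Collect evaluation reports into a comparison table
#'
#' One row per (component, method) in the layout of a quantitative-model
#' comparison table: Rc, RMSEC, Rp, RMSEP, SEP, Bias.
#'
#' @param reports named list: `reports[[component]][[method]]` is an
#'   [evaluate_model()] report.
#' @return data.frame with columns component, method, Rc, RMSEC, Rp,
#'   RMSEP, SEP, Bias.
#' @export
report_table <- function(reports) {
  rows <- list()
  for (comp in names(reports)) {
    for (meth in names(reports[[comp]])) {
      r <- reports[[comp]][[meth]]
      rows[[length(rows) + 1L]] <- data.frame(
        component = comp, method = meth,
        Rc = r$Rc, RMSEC = r$RMSEC, Rp = r$Rp, RMSEP = r$RMSEP,
        SEP = r$SEP, Bias = r$Bias)
    }
  }
  do.call(rbind, rows)
}
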