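#' Frequency-consensus segment selection over repeated BPSO runs
#'
#' Executes `n_runs` independent, individually seeded BPSO runs and counts,
#' for each bit (segment), how many runs ended with that bit set in their
#' final global-best mask. A segment enters the final selection when its
#' count strictly exceeds `threshold` — with the defaults, when it is
#' selected in more than 50 of 100 runs. Repeated runs plus the majority
#' rule damp the run-to-run variability of a single stochastic optimizer.
#'
#' @param fitness_factory function of the run index (1..n_runs) returning
#'   that run's fitness function (a function of a 0/1 mask). A factory is
#'   used so each run can carry its own memoization cache.
#' @param n_bits number of bits (segments).
#' @param cfg a [bpso_config()]; `cfg$seed` is the base seed from which
#'   each run's stream seed is derived.
#' @param n_runs number of optimizer runs (default 100).
#' @param threshold strict count threshold (default 50).
#' @return Object of class `consensus_result`: list with `n_runs`,
#'   `threshold`, `counts` (per-segment selection frequency), `selected`
#'   (0/1 vector, `counts > threshold`), `runs` (list of `bpso_run`).
#' @export
run_consensus <- function(fitness_factory, n_bits, cfg = bpso_config(),
                          n_runs = 100L, threshold = 50L) {
  stopifnot(is.function(fitness_factory), n_runs >= 1,
            threshold >= 0, threshold <= n_runs)
  runs <- vector("list", n_runs)
  counts <- integer(n_bits)
  for (r in seq_len(n_runs)) {
    fitness <- fitness_factory(r)
    if (!is.function(fitness))
      stop("fitness_factory must return a function", call. = FALSE)
    run_cfg <- cfg
    run_cfg$seed <- derive_seed(cfg$seed, r)
    runs[[r]] <- tryCatch(run_bpso(fitness, n_bits, run_cfg),
                          error = function(e)
                            stop(sprintf("BPSO run %d failed: %s", r,
                                         conditionMessage(e)),
                                 call. = FALSE))
    counts <- counts + as.integer(runs[[r]]$best_position)
  }
  structure(list(n_runs = as.integer(n_runs),
                 threshold = as.integer(threshold),
                 counts = counts,
                 selected = as.integer(counts > threshold),
                 runs = runs),
            class = "consensus_result")
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(sprintf("consensus_result: %d runs, threshold >%d, %d/%d segments selected\n",
              x$n_runs, x$threshold, sum(x$selected), length(x$counts)))
  invisible(x)
}

#' Write the per-segment selection-count table as CSV
#'
#' @param res a [run_consensus()] result.
#' @param path output CSV path.
#' @return `invisible(path)`.
#' @export
write_segment_counts_csv <- function(res, path) {
  df <- data.frame(segment = seq_along(res$counts), count = res$counts,
                   selected = res$selected)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Refit a calibration model on the consensus-selected variables
#'
#' Restricts the predictor matrix to the variables covered by the selected
#' segments, fits the model on the calibration portion (all folds except
#' `pred_fold`), and evaluates the six-figure report with `pred_fold` as
#' the prediction set.
#'
#' @param selected 0/1 vector over segments (non-empty).
#' @param X full predictor matrix.
#' @param y response vector.
#' @param scheme a [make_segments()] scheme for `ncol(X)`.
#' @param spec a [pls_spec()] or [svr_spec()].
#' @param folds a [tenfold_split()] assignment for `nrow(X)`.
#' @param pred_fold fold id used as the prediction set (default 1).
#' @return list with `model` (fitted on calibration samples and selected
#'   variables) and `report` (an [evaluate_model()] report).
#' @export
consensus_refit <- function(selected, X, y, scheme, spec, folds,
                            pred_fold = 1L) {
  vars <- mask_to_variables(selected, scheme)
  if (length(vars) == 0L)
    stop("empty segment selection: nothing to refit", call. = FALSE)
  X <- as.matrix(X)
  stopifnot(ncol(X) == scheme$n_vars, inherits(folds, "fold_assignment"),
            nrow(X) == folds$n_samples, pred_fold %in% seq_len(folds$n_folds))
  Xs <- X[, vars, drop = FALSE]
  test <- folds$fold_of == pred_fold
  model <- fit_model(spec, Xs[!test, , drop = FALSE], y[!test])
  report <- evaluate_model(model, Xs[!test, , drop = FALSE], y[!test],
                           Xs[test, , drop = FALSE], y[test])
  list(model = model, report = report)
}
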