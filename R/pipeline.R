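#' Memoized segment-subset cross-validation fitness
#'
#' Builds the BPSO objective for wavelength-segment selection: the fitness
#' of a segment bitmask is the tenfold RMSECV of the calibration model
#' refit on the variables covered by the selected segments. The all-zeros
#' mask is assigned `Inf` (an empty wavelength set cannot calibrate), so
#' the optimizer never returns an empty selection. Fitness values are
#' cached per mask, since a converging swarm revisits masks often.
#'
#' For a PLS spec the latent-variable count is re-selected for every mask:
#' `spec$n_latent` acts as the search cap, and the fitness is the best
#' RMSECV over 1..cap latent variables (all truncations come out of one
#' NIPALS pass per fold, so this costs little more than a fixed count).
#' Re-selecting per subset matters: a latent count tuned to the full
#' spectrum overfits small masks, which would bias the search toward
#' including uninformative segments as incidental regularizers.
#'
#' @param X calibration predictor matrix (pretreated spectra).
#' @param y calibration response.
#' @param scheme a [make_segments()] scheme for `ncol(X)`.
#' @param spec a [pls_spec()] or [svr_spec()].
#' @param folds inner fold assignment for `nrow(X)` samples.
#' @return function(mask) -> fitness, with attribute `"cache"` (an
#'   environment mapping mask keys to values).
#' @export
segment_cv_fitness <- function(X, y, scheme, spec, folds) {
  X <- as.matrix(X)
  stopifnot(ncol(X) == scheme$n_vars)
  cache <- new.env(parent = emptyenv())
  min_train <- folds$n_samples - max(tabulate(folds$fold_of, folds$n_folds))
  f <- function(mask) {
    key <- paste(as.integer(mask != 0), collapse = "")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    vars <- mask_to_variables(mask, scheme)
    val <- if (length(vars) == 0L) Inf else if (spec$kind == "pls") {
      cap <- min(spec$n_latent, length(vars), min_train - 1L)
      resid <- pls_cv_resid_all_cpp(X[, vars, drop = FALSE], y,
                                    as.integer(folds$fold_of),
                                    folds$n_folds, cap)
      min(sqrt(.colMeans(resid^2, nrow(resid), ncol(resid))))
    } else {
      cv_rmse(spec, X[, vars, drop = FALSE], y, folds)
    }
    cache[[key]] <- val
    val
  }
  attr(f, "cache") <- cache
  f
}

experiment_profiles <- list(
  ci = list(max_generations = 30L, n_runs = 20L, threshold = 10L),
  full = list(max_generations = 100L, n_runs = 100L, threshold = 50L))

#' Run the full calibration experiment
#'
#' Orchestrates, per component and method: SNV pretreatment, an outer
#' tenfold split whose designated fold is the prediction set (the other
#' nine folds form the calibration set), baseline PLS/SVR fits on the full
#' spectrum, and BPSO-consensus wavelength selection followed by a refit
#' on the selected segments — then the six-figure evaluation report for
#' every (component, method) cell.
#'
#' The BPSO fitness is the tenfold RMSECV on the calibration set only;
#' the prediction set never enters selection or fitting. Each consensus
#' run evaluates fitness under its own seeded inner fold assignment, so
#' the majority rule damps segments that look helpful only under a
#' particular split. For PLS methods the latent-variable count is chosen
#' by inner cross-validation — per mask inside the swarm fitness (see
#' [segment_cv_fitness()]) and again on the selected variables for the
#' final refit.
#'
#' Two profiles are provided: `"full"` (100 consensus runs of 100
#' generations, threshold 50) and the lighter `"ci"` default (20 runs of
#' 30 generations, threshold 10 — the same strict-majority rule).
#'
#' @param spectra a [spectra_set()], or NULL when `sim` is given.
#' @param references named list of [reference_table()], or NULL.
#' @param sim optional [sim_config()]; when given, data are simulated and
#'   `spectra`/`references` are taken from the simulation.
#' @param components character vector of component names to analyze
#'   (default: all available).
#' @param methods subset of `c("pls", "svr", "bpso_pls", "bpso_svr")`.
#' @param n_segments number of wavenumber segments (default 21).
#' @param profile `"ci"` or `"full"`; sets BPSO generations, consensus
#'   runs and threshold unless overridden.
#' @param swarm_size,c1,c2,v_max,inertia_weight BPSO parameters.
#' @param max_generations,n_runs,threshold optional overrides of the
#'   profile.
#' @param seed master seed; all fold assignments and BPSO streams derive
#'   from it.
#' @param pred_fold outer fold id held out as the prediction set.
#' @param max_latent cap for PLS latent-variable selection.
#' @param svr_C,svr_epsilon linear-SVR parameters.
#' @param snv_ddof sd denominator convention for SNV (1 or 0).
#' @param do_average_replicates average replicate scans first (requires a
#'   replicate map on the spectra).
#' @param outdir optional directory; when given, CSV/JSON reports are
#'   written there.
#' @param verbose emit one log line per (component, method, stage).
#' @return list of class `nir_experiment` with elements `results`
#'   (per-component, per-method: `report`, and for BPSO methods
#'   `consensus`, `selected`, `ranges`, `n_latent`), `table` (the
#'   comparison data.frame), `manifest` (all seeds and settings), and for
#'   simulated data `truth`.
#' @export
run_experiment <- function(spectra = NULL, references = NULL, sim = NULL,
                           components = NULL,
                           methods = c("pls", "bpso_pls"),
                           n_segments = 21L,
                           profile = c("ci", "full"),
                           swarm_size = 20L, c1 = 2, c2 = 2, v_max = 6,
                           inertia_weight = 1.0,
                           max_generations = NULL, n_runs = NULL,
                           threshold = NULL,
                           seed = 1L, pred_fold = 1L, max_latent = 15L,
                           svr_C = 1, svr_epsilon = 0.1, snv_ddof = 1,
                           do_average_replicates = FALSE,
                           outdir = NULL, verbose = FALSE) {
  profile <- match.arg(profile)
  prof <- experiment_profiles[[profile]]
  if (is.null(max_generations)) max_generations <- prof$max_generations
  if (is.null(n_runs)) n_runs <- prof$n_runs
  if (is.null(threshold)) threshold <- prof$threshold
  methods <- match.arg(methods, c("pls", "svr", "bpso_pls", "bpso_svr"),
                       several.ok = TRUE)
  truth <- NULL
  if (!is.null(sim)) {
    d <- simulate_nir(sim)
    spectra <- d$spectra
    references <- d$references
    truth <- d$truth
  }
  if (is.null(spectra) || is.null(references))
    stop("provide either spectra + references or a sim config",
         call. = FALSE)
  if (do_average_replicates) spectra <- average_replicates(spectra)
  if (is.null(components)) components <- names(references)
  stopifnot(length(components) >= 1, length(methods) >= 1,
            all(components %in% names(references)))
  log_line <- function(comp, meth, stage, ...) {
    if (verbose)
      message(sprintf("component=%s method=%s stage=%s %s", comp, meth,
                      stage, sprintf(...)))
  }
  results <- list()
  for (ci_comp in seq_along(components)) {
    comp <- components[ci_comp]
    al <- align_spectra(spectra, references[[comp]])
    Xall <- snv(al$spectra, ddof = snv_ddof)$absorbance
    y <- unname(al$reference$values)
    n <- nrow(Xall)
    scheme <- make_segments(ncol(Xall), n_segments)
    folds <- tenfold_split(n, 10L, seed)
    test <- folds$fold_of == pred_fold
    Xcal <- Xall[!test, , drop = FALSE]; ycal <- y[!test]
    inner <- tenfold_split(sum(!test), 10L, derive_seed(seed, 101L))
    comp_res <- list(folds = folds, scheme = scheme, X = Xall, y = y,
                     inner_seed = inner$seed, pred_fold = pred_fold)
    n_lat_full <- NULL
    if ("pls" %in% methods) {
      n_lat_full <- choose_n_latent(Xcal, ycal, inner, max_latent)
      log_line(comp, "pls", "choose_n_latent", "n_latent=%d", n_lat_full)
    }
    for (meth in methods) {
      comp_res[[meth]] <- tryCatch({
        if (meth == "pls") {
          m <- fit_pls(Xcal, ycal, n_lat_full)
          list(report = evaluate_model(m, Xcal, ycal,
                                       Xall[test, , drop = FALSE], y[test]),
               n_latent = n_lat_full)
        } else if (meth == "svr") {
          m <- fit_svr(Xcal, ycal, C = svr_C, epsilon = svr_epsilon)
          list(report = evaluate_model(m, Xcal, ycal,
                                       Xall[test, , drop = FALSE], y[test]))
        } else {
          base_spec <- if (meth == "bpso_pls") pls_spec(max_latent)
                       else svr_spec(svr_C, svr_epsilon)
          # each consensus run draws its own inner fold assignment, so
          # segments that help only under one particular split do not
          # accumulate counts across runs
          factory <- function(r)
            segment_cv_fitness(Xcal, ycal, scheme, base_spec,
                               tenfold_split(sum(!test), 10L,
                                             derive_seed(inner$seed, r)))
          fitness <- segment_cv_fitness(Xcal, ycal, scheme, base_spec,
                                        inner)
          cfg <- bpso_config(swarm_size = swarm_size, c1 = c1, c2 = c2,
                             max_generations = max_generations,
                             v_max = v_max,
                             inertia_weight = inertia_weight,
                             seed = derive_seed(seed,
                                                1000L * ci_comp +
                                                  match(meth, methods)))
          cons <- run_consensus(factory, scheme$n_segments,
                                cfg, n_runs = n_runs,
                                threshold = threshold)
          log_line(comp, meth, "consensus", "selected=%d/%d",
                   sum(cons$selected), scheme$n_segments)
          if (sum(cons$selected) == 0L)
            stop("consensus selected no segment (max count ",
                 max(cons$counts), " <= threshold ", threshold, ")",
                 call. = FALSE)
          vars <- mask_to_variables(cons$selected, scheme)
          refit_spec <- if (meth == "bpso_pls") {
            pls_spec(choose_n_latent(Xcal[, vars, drop = FALSE], ycal,
                                     inner, max_latent))
          } else base_spec
          rf <- consensus_refit(cons$selected, Xall, y, scheme,
                                refit_spec, folds, pred_fold)
          list(report = rf$report, consensus = cons,
               selected = cons$selected,
               ranges = segments_to_wavenumber_ranges(
                 cons$selected, scheme, al$spectra$wavenumbers),
               fitness_of_selected = fitness(cons$selected),
               n_latent = if (meth == "bpso_pls") refit_spec$n_latent,
               model = rf$model)
        }
      }, error = function(e) {
        log_line(comp, meth, "failed", "%s", conditionMessage(e))
        list(error = conditionMessage(e))
      })
      if (is.null(comp_res[[meth]]$error))
        log_line(comp, meth, "report", "Rp=%.4f RMSEP=%.4f",
                 comp_res[[meth]]$report$Rp, comp_res[[meth]]$report$RMSEP)
    }
    results[[comp]] <- comp_res
  }
  reports <- lapply(results, function(cr)
    Filter(Negate(is.null),
           lapply(cr[intersect(methods, names(cr))], function(m)
             if (is.null(m$error)) m$report)))
  manifest <- list(seed = as.integer(seed), profile = profile,
                   methods = methods, components = components,
                   n_segments = as.integer(n_segments),
                   bpso = list(swarm_size = as.integer(swarm_size),
                               c1 = c1, c2 = c2,
                               max_generations = as.integer(max_generations),
                               v_max = v_max,
                               inertia_weight = inertia_weight),
                   consensus = list(n_runs = as.integer(n_runs),
                                    threshold = as.integer(threshold)),
                   pred_fold = as.integer(pred_fold),
                   max_latent = as.integer(max_latent),
                   svr = list(C = svr_C, epsilon = svr_epsilon),
                   snv_ddof = snv_ddof,
                   package_version =
                     as.character(utils::packageVersion("nirselect")))
  out <- structure(list(results = results, table = report_table(reports),
                        manifest = manifest, truth = truth),
                   class = "nir_experiment")
  if (!is.null(outdir)) write_experiment(out, outdir)
  out
}

#' @export
print.nir_experiment <- function(x, ...) {
  cat("nir_experiment:", paste(x$manifest$components, collapse = ", "),
      "x", paste(x$manifest$methods, collapse = ", "), "\n")
  df <- x$table
  df[, 3:8] <- round(df[, 3:8], 4)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write an experiment's report bundle to disk
#'
#' Emits the comparison table, per-segment selection counts, per-run
#' convergence curves, selected wavenumber ranges, prediction-set
#' predicted-vs-actual pairs, and a JSON manifest of all seeds and
#' settings.
#'
#' @param exp a [run_experiment()] result.
#' @param outdir output directory (created if missing).
#' @return `invisible(outdir)`.
#' @export
write_experiment <- function(exp, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(exp$table, file.path(outdir, "model_comparison.csv"),
                   row.names = FALSE)
  ranges <- list()
  for (comp in names(exp$results)) {
    cr <- exp$results[[comp]]
    for (meth in names(cr)) {
      m <- cr[[meth]]
      if (!is.list(m) || !is.null(m$error)) next
      if (!is.null(m$consensus)) {
        write_segment_counts_csv(m$consensus,
          file.path(outdir, sprintf("segment_counts_%s_%s.csv", comp, meth)))
        write_convergence_csv(m$consensus$runs,
          file.path(outdir, sprintf("convergence_%s_%s.csv", comp, meth)))
        ranges[[paste(comp, meth, sep = "_")]] <- m$ranges
      }
      if (!is.null(m$report)) {
        utils::write.csv(
          data.frame(sample = seq_along(m$report$actual),
                     actual = m$report$actual,
                     predicted = m$report$predicted),
          file.path(outdir, sprintf("prediction_%s_%s.csv", comp, meth)),
          row.names = FALSE)
      }
    }
  }
  if (length(ranges))
    write_selected_ranges_csv(ranges,
                              file.path(outdir, "selected_ranges.csv"))
  jsonlite::write_json(exp$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(outdir)
}
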