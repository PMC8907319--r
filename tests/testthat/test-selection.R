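test_that("consensus counts and the strict majority rule behave as stated", {
  target <- c(1, 0, 1, 1, 0, 0, 1, 0)
  factory <- function(r) function(m) sum(m != target)
  cfg <- bpso_config(seed = 5, max_generations = 40)
  cons <- run_consensus(factory, 8, cfg, n_runs = 12, threshold = 6)
  expect_identical(length(cons$counts), 8L)
  expect_true(all(cons$counts >= 0 & cons$counts <= 12))
  expect_identical(cons$selected, as.integer(cons$counts > 6))
  # counts sum equals total set bits over the runs' best masks
  popcounts <- vapply(cons$runs, function(r) sum(r$best_position),
                      numeric(1))
  expect_identical(sum(cons$counts), as.integer(sum(popcounts)))
  # the easy optimum dominates: every target bit above threshold
  expect_true(all(cons$counts[target == 1] > 6))
  expect_true(all(cons$counts[target == 0] < 6))
})

test_that("threshold boundaries are strict and single-run consensus is its mask", {
  # craft counts at the boundary through degenerate deterministic fitness:
  # fitness pins bit 1 to one, leaves others at zero
  factory <- function(r) function(m) {
    if (m[1] == 0) return(10)
    sum(m[-1])
  }
  cons1 <- run_consensus(factory, 4, bpso_config(seed = 2,
                                                 max_generations = 25),
                         n_runs = 1, threshold = 0)
  expect_identical(cons1$selected, as.integer(cons1$runs[[1]]$best_position))
  # synthetic check of the rule itself at count == threshold
  cons_fake <- structure(list(n_runs = 100L, threshold = 50L,
                              counts = c(50L, 51L),
                              selected = as.integer(c(50L, 51L) > 50L)),
                         class = "consensus_result")
  expect_identical(cons_fake$selected, c(0L, 1L))
})

test_that("consensus is reproducible from the base seed", {
  target <- c(1, 1, 0, 0, 1)
  factory <- function(r) function(m) sum(m != target)
  cfg <- bpso_config(seed = 31, max_generations = 15)
  c1 <- run_consensus(factory, 5, cfg, n_runs = 6, threshold = 3)
  c2 <- run_consensus(factory, 5, cfg, n_runs = 6, threshold = 3)
  expect_identical(c1$counts, c2$counts)
  expect_identical(c1$selected, c2$selected)
})

test_that("refit on all segments reduces to the full-spectrum baseline", {
  cfg <- single_band_config(n_vars = 120, n_samples = 50, seed = 21)
  d <- simulate_nir(cfg)
  X <- d$spectra$absorbance
  y <- unname(d$references$moisture$values)
  scheme <- make_segments(120, 6)
  folds <- tenfold_split(50, 10, 13)
  rf <- consensus_refit(rep(1, 6), X, y, scheme, pls_spec(3), folds,
                        pred_fold = 1)
  test <- folds$fold_of == 1
  m_base <- fit_pls(X[!test, ], y[!test], 3)
  base_rep <- evaluate_model(m_base, X[!test, ], y[!test],
                             X[test, , drop = FALSE], y[test])
  expect_equal(rf$report$RMSEP, base_rep$RMSEP, tolerance = 1e-12)
  expect_equal(rf$report$Rc, base_rep$Rc, tolerance = 1e-12)
  # single-segment refit sees exactly that segment's width
  rf1 <- consensus_refit(c(1, rep(0, 5)), X, y, scheme, pls_spec(2), folds)
  expect_identical(rf1$model$n_vars, 20L)
  expect_error(consensus_refit(rep(0, 6), X, y, scheme, pls_spec(2), folds),
               "empty")
})

test_that("refit on planted segments beats refit on their complement", {
  cfg <- single_band_config(n_vars = 210, n_samples = 60, seed = 33)
  d <- simulate_nir(cfg)
  X <- d$spectra$absorbance
  y <- unname(d$references$moisture$values)
  scheme <- make_segments(210, 21)
  planted <- planted_segments(cfg, scheme)$moisture
  m_in <- m_out <- rep(0, 21)
  m_in[planted] <- 1
  m_out[-planted] <- 1
  folds <- tenfold_split(60, 10, 3)
  r_in <- consensus_refit(m_in, X, y, scheme, pls_spec(4), folds)$report
  r_out <- consensus_refit(m_out, X, y, scheme, pls_spec(4), folds)$report
  expect_lt(r_in$RMSEP, r_out$RMSEP)
})

test_that("consensus recovers every planted segment of a clean signal", {
  cfg <- single_band_config(n_vars = 210, n_samples = 60, seed = 44)
  d <- simulate_nir(cfg)
  X <- d$spectra$absorbance
  y <- unname(d$references$moisture$values)
  scheme <- make_segments(210, 21)
  planted <- planted_segments(cfg, scheme)$moisture
  factory <- function(r)
    segment_cv_fitness(X, y, scheme, pls_spec(8),
                       tenfold_split(60, 10, 500 + r))
  cons <- run_consensus(factory, 21,
                        bpso_config(seed = 7, max_generations = 15),
                        n_runs = 8, threshold = 4)
  expect_true(all(cons$counts[planted] > 4))
})
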