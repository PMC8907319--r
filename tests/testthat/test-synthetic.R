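test_that("the default tea configuration matches the published statistics", {
  cfg <- default_tea_config(seed = 1)
  names(cfg$components) <- vapply(cfg$components, `[[`, "", "name")
  expect_identical(cfg$components$moisture$concentration_range,
                   c(3.76, 6.29))
  expect_identical(cfg$components$caffeine$concentration_range,
                   c(0.48, 2.80))
  expect_identical(cfg$components$tea_polyphenols$concentration_range,
                   c(18.70, 22.40))
  expect_identical(cfg$components$tea_polysaccharides$concentration_range,
                   c(18.00, 24.50))
  # caffeine bands sit inside the caffeine characteristic regions
  for (b in cfg$components$caffeine$bands) {
    in_region <- (b$center >= 4000 && b$center <= 4894) ||
      (b$center >= 6994 && b$center <= 7293)
    expect_true(in_region)
  }
  # all band centers on the grid
  for (comp in cfg$components)
    for (b in comp$bands)
      expect_true(b$center <= 10000 && b$center >= 4000)
  expect_identical(cfg$grid, c(10000, 4000, 6539))
})

test_that("simulation is linear in concentration and seed-reproducible", {
  comp <- component_spec("x", c(1, 9), list(band_spec(7000, 100, 0.01)))
  cfg <- sim_config(n_samples = 5, grid = c(10000, 4000, 200),
                    components = list(comp), scatter_gain_range = c(1, 1),
                    scatter_offset_range = c(0, 0), baseline_amplitude = 0,
                    noise_sd = 0, background = NULL, seed = 3)
  d <- simulate_nir(cfg)
  shape <- 0.01 * exp(-0.5 * ((cfg$wavenumbers - 7000) / 100)^2)
  for (i in 1:5)
    expect_equal(unname(d$spectra$absorbance[i, ]),
                 d$truth$concentrations[i, 1] * shape, tolerance = 1e-12)
  d2 <- simulate_nir(cfg)
  expect_identical(d$spectra$absorbance, d2$spectra$absorbance)
  expect_identical(d$truth$concentrations, d2$truth$concentrations)
})

test_that("SNV cancels the simulated multiplicative scatter exactly", {
  comp <- component_spec("x", c(1, 9), list(band_spec(6000, 150, 0.02)))
  base <- list(n_samples = 20, grid = c(10000, 4000, 300),
               components = list(comp), baseline_amplitude = 0,
               noise_sd = 0, background = NULL, seed = 8)
  with_scatter <- do.call(sim_config, c(base, list(
    scatter_gain_range = c(0.7, 1.3), scatter_offset_range = c(-0.2, 0.2))))
  no_scatter <- do.call(sim_config, c(base, list(
    scatter_gain_range = c(1, 1), scatter_offset_range = c(0, 0))))
  ds <- simulate_nir(with_scatter)
  dn <- simulate_nir(no_scatter)
  # same concentrations (same seed, same draw order), different distortion
  expect_identical(ds$truth$concentrations, dn$truth$concentrations)
  expect_lt(max(abs(snv(ds$spectra)$absorbance -
                      snv(dn$spectra)$absorbance)), 1e-10)
})

test_that("concentration marginals respect the configured ranges", {
  cfg <- default_tea_config(seed = 6, n_samples = 1000, n_vars = 50)
  d <- simulate_nir(cfg)
  for (j in seq_along(cfg$components)) {
    rng <- cfg$components[[j]]$concentration_range
    x <- d$truth$concentrations[, j]
    expect_gte(min(x), rng[1])
    expect_lte(max(x), rng[2])
    # uniform mean: midpoint within 3 standard errors
    se <- diff(rng) / sqrt(12) / sqrt(1000)
    expect_lt(abs(mean(x) - mean(rng)), 3 * se)
  }
})

test_that("planted segments cover each band and respect its region", {
  cfg <- default_tea_config(seed = 2, n_vars = 654)
  scheme <- make_segments(654, 21)
  ps <- planted_segments(cfg, scheme)
  expect_identical(names(ps),
                   c("moisture", "caffeine", "tea_polyphenols",
                     "tea_polysaccharides"))
  wn <- cfg$wavenumbers
  for (j in seq_along(cfg$components)) {
    comp <- cfg$components[[j]]
    expect_gt(length(ps[[j]]), 0)
    for (b in comp$bands) {
      covering <- Filter(function(d) {
        i1 <- scheme$boundaries[d, "start"] + 1L
        i2 <- scheme$boundaries[d, "end"]
        min(wn[c(i1, i2)]) <= b$center + 2.5 * b$width &&
          max(wn[c(i1, i2)]) >= b$center - 2.5 * b$width
      }, seq_len(scheme$n_segments))
      expect_true(all(unlist(covering) %in% ps[[j]]))
      expect_true(length(covering) > 0)
    }
  }
  # a band fully inside one segment maps to exactly that segment
  comp1 <- component_spec("z", c(1, 2), list(band_spec(9900, 5, 0.01)))
  cfg1 <- sim_config(n_samples = 3, grid = c(10000, 4000, 654),
                     components = list(comp1), seed = 1)
  expect_identical(planted_segments(cfg1, scheme)$z, 1L)
  # a band straddling a boundary maps to both neighbors
  b_edge <- wn[scheme$boundaries[1, "end"]]  # first var of segment 2
  comp2 <- component_spec("z", c(1, 2),
                          list(band_spec(b_edge, 30, 0.01)))
  cfg2 <- sim_config(n_samples = 3, grid = c(10000, 4000, 654),
                     components = list(comp2), seed = 1)
  expect_identical(planted_segments(cfg2, scheme)$z, c(1L, 2L))
})

test_that("a simulated dataset round trips through its disk bundle", {
  cfg <- default_tea_config(seed = 13, n_samples = 6, n_vars = 40)
  d <- simulate_nir(cfg)
  dir <- withr::local_tempdir()
  write_simulation(d, dir)
  s2 <- read_spectra_csv(file.path(dir, "spectra.csv"))
  expect_lt(max(abs(s2$absorbance - d$spectra$absorbance)), 1e-12)
  r2 <- read_reference_csv(file.path(dir, "references.csv"), "caffeine")
  expect_equal(unname(r2$values),
               unname(d$references$caffeine$values), tolerance = 1e-12)
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"))
  expect_identical(length(gt$components), 4L)
  expect_identical(gt$seed, 13L)
})

test_that("band centers outside the grid are rejected", {
  comp <- component_spec("x", c(1, 2), list(band_spec(3500, 50, 0.01)))
  expect_error(sim_config(n_samples = 3, grid = c(10000, 4000, 100),
                          components = list(comp)), "outside the grid")
})
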