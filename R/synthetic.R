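#' Gaussian absorption band specification
#'
#' @param center band center, cm^-1 (must lie on the simulation grid).
#' @param width Gaussian standard deviation, cm^-1.
#' @param amplitude peak absorbance contributed per percent of component
#'   content (Beer-Lambert proportionality).
#' @return list of class `band_spec`.
#' @export
band_spec <- function(center, width, amplitude) {
  stopifnot(width > 0, amplitude > 0)
  structure(list(center = center, width = width, amplitude = amplitude),
            class = "band_spec")
}

#' Component specification for the spectra simulator
#'
#' @param name component name.
#' @param concentration_range `c(min, max)` content in percent, min < max.
#' @param bands list of [band_spec()] objects (at least one).
#' @param concentration_mean,concentration_sd optional moments for the
#'   truncated-normal concentration option.
#' @return list of class `component_spec`.
#' @export
component_spec <- function(name, concentration_range, bands,
                           concentration_mean = NULL,
                           concentration_sd = NULL) {
  stopifnot(length(concentration_range) == 2,
            concentration_range[1] < concentration_range[2],
            length(bands) >= 1)
  structure(list(name = name,
                 concentration_range = as.numeric(concentration_range),
                 bands = bands,
                 concentration_mean = concentration_mean,
                 concentration_sd = concentration_sd),
            class = "component_spec")
}

#' Simulation configuration
#'
#' Describes a synthetic NIR dataset: a wavenumber grid, a set of
#' absorbing components with Gaussian bands, a fixed broad background
#' spectrum (the non-varying sample matrix), per-sample multiplicative
#' scatter gain, additive offset, a low-order random baseline, and iid
#' Gaussian instrument noise. The observation model per sample is
#' \deqn{x = g (x_{clean} + baseline) + o + \varepsilon,}
#' where `x_clean = background + sum_j c_j * bands_j` is linear in the
#' concentrations `c_j`, `g` and `o` are the per-sample gain and offset
#' (exactly what SNV is designed to remove), and `epsilon` is
#' N(0, noise_sd^2).
#'
#' @param n_samples number of samples.
#' @param grid `c(high, low, n_vars)`: wavenumber range in cm^-1
#'   (descending) and number of evenly spaced grid points.
#' @param components list of [component_spec()].
#' @param scatter_gain_range per-sample uniform gain range (> 0).
#' @param scatter_offset_range per-sample uniform additive offset range.
#' @param baseline_amplitude scale of the random degree-<=2 polynomial
#'   baseline (0 disables it).
#' @param noise_sd instrument noise standard deviation (absorbance units).
#' @param concentration_dist `"uniform"` (default) over the ranges, or
#'   `"truncnorm"` using each component's mean/sd truncated to its range.
#' @param background function(wavenumbers) -> baseline matrix absorbance,
#'   or NULL for none.
#' @param seed integer seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples, grid = c(10000, 4000, 6539), components,
                       scatter_gain_range = c(0.9, 1.1),
                       scatter_offset_range = c(-0.05, 0.05),
                       baseline_amplitude = 0.01, noise_sd = 0.002,
                       concentration_dist = c("uniform", "truncnorm"),
                       background = NULL, seed = 1L) {
  stopifnot(n_samples >= 1, length(grid) == 3, grid[1] > grid[2],
            grid[3] >= 2, all(scatter_gain_range > 0),
            noise_sd >= 0, baseline_amplitude >= 0)
  concentration_dist <- match.arg(concentration_dist)
  wn <- seq(grid[1], grid[2], length.out = grid[3])
  for (comp in components) {
    for (b in comp$bands) {
      if (b$center > grid[1] || b$center < grid[2])
        stop("band center ", b$center, " cm-1 of component '", comp$name,
             "' is outside the grid range", call. = FALSE)
    }
  }
  structure(list(n_samples = as.integer(n_samples), grid = grid,
                 wavenumbers = wn, components = components,
                 scatter_gain_range = scatter_gain_range,
                 scatter_offset_range = scatter_offset_range,
                 baseline_amplitude = baseline_amplitude,
                 noise_sd = noise_sd,
                 concentration_dist = concentration_dist,
                 background = background, seed = as.integer(seed)),
            class = "sim_config")
}

# Broad, smooth matrix-absorption background typical of dried plant
# material: overlapping wide bands plus a gentle slope toward low
# wavenumbers. Fixed across samples; it anchors the absolute scale of the
# spectra so that SNV-normalized spectra remain informative about absolute
# (not just relative) concentrations.
default_background <- function(wn) {
  0.40 * exp(-0.5 * ((wn - 5200) / 700)^2) +
    0.30 * exp(-0.5 * ((wn - 7000) / 900)^2) +
    0.20 * exp(-0.5 * ((wn - 8800) / 800)^2) +
    0.10 * (10000 - wn) / 6000
}

#' Default instant-tea simulation configuration
#'
#' Four components with content ranges matching the composition statistics
#' of the 118-sample instant-tea dataset (moisture 3.76-6.29%, caffeine
#' 0.48-2.80%, tea polyphenols 18.70-22.40%, tea polysaccharides
#' 18.00-24.50%) and Gaussian absorption bands centered inside each
#' component's characteristic wavenumber regions (e.g. moisture within
#' 6694-7293 and 7892-8193 cm^-1, caffeine within 4000-4894 and 6994-7293
#' cm^-1). Polyphenol and polysaccharide bands deliberately share regions
#' with each other and with moisture (7893-8193, 7001-7293), so those two
#' components are harder to calibrate — their per-percent amplitudes are
#' also smaller, since their absolute contents are an order of magnitude
#' higher.
#'
#' @param seed integer seed.
#' @param n_samples number of samples (default 118).
#' @param n_vars grid size (default 6539 points from 10,000 to 4,000
#'   cm^-1, which a 21-segment scheme splits into twenty segments of 311
#'   variables plus one of 319).
#' @param noise_sd instrument noise sd (default 0.002 absorbance units).
#' @return a [sim_config()].
#' @export
default_tea_config <- function(seed = 1L, n_samples = 118L, n_vars = 6539L,
                               noise_sd = 0.002) {
  comps <- list(
    component_spec("moisture", c(3.76, 6.29),
                   list(band_spec(7000, 50, 0.020),
                        band_spec(8040, 50, 0.016)),
                   concentration_mean = 4.79, concentration_sd = 0.60),
    component_spec("caffeine", c(0.48, 2.80),
                   list(band_spec(4610, 60, 0.020),
                        band_spec(7075, 26, 0.014)),
                   concentration_mean = 1.69, concentration_sd = 1.65),
    component_spec("tea_polyphenols", c(18.70, 22.40),
                   list(band_spec(4660, 70, 0.0035),
                        band_spec(5000, 70, 0.0030),
                        band_spec(6850, 60, 0.0030),
                        band_spec(7440, 55, 0.0030),
                        band_spec(8040, 55, 0.0025)),
                   concentration_mean = 20.93, concentration_sd = 0.89),
    component_spec("tea_polysaccharides", c(18.00, 24.50),
                   list(band_spec(4700, 60, 0.0030),
                        band_spec(6100, 80, 0.0035),
                        band_spec(7150, 50, 0.0025),
                        band_spec(8050, 60, 0.0025),
                        band_spec(9100, 80, 0.0035),
                        band_spec(9850, 55, 0.0030)),
                   concentration_mean = 21.18, concentration_sd = 2.17))
  sim_config(n_samples = n_samples, grid = c(10000, 4000, n_vars),
             components = comps, noise_sd = noise_sd,
             background = default_background, seed = seed)
}

#' Simulate a synthetic NIR dataset
#'
#' Draws per-sample concentrations, builds clean spectra by Beer-Lambert
#' superposition of Gaussian bands on the fixed background, applies
#' per-sample multiplicative gain, additive offset, a random low-order
#' baseline and iid noise, and returns the observed spectra together with
#' reference tables and the generating ground truth. Fully reproducible
#' from `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `spectra` (a [spectra_set()]), `references` (named
#'   list of [reference_table()], one per component), and `truth` (list:
#'   `concentrations` matrix samples x components, `clean` noiseless
#'   spectra matrix, `gain`, `offset`, `config`).
#' @export
simulate_nir <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  wn <- cfg$wavenumbers
  n <- cfg$n_samples
  k <- length(cfg$components)
  ids <- sprintf("S%03d", seq_len(n))
  with_seed(cfg$seed, {
    conc <- matrix(0, n, k,
                   dimnames = list(ids,
                                   vapply(cfg$components, `[[`, "",
                                          "name")))
    for (j in seq_len(k)) {
      comp <- cfg$components[[j]]
      rng <- comp$concentration_range
      if (cfg$concentration_dist == "uniform" ||
          is.null(comp$concentration_mean)) {
        conc[, j] <- stats::runif(n, rng[1], rng[2])
      } else {
        # truncated normal by rejection; ranges are a few sd wide so this
        # terminates quickly
        x <- numeric(0)
        while (length(x) < n) {
          draw <- stats::rnorm(2L * n, comp$concentration_mean,
                               comp$concentration_sd)
          x <- c(x, draw[draw >= rng[1] & draw <= rng[2]])
        }
        conc[, j] <- x[seq_len(n)]
      }
    }
    # pure-component spectra (absorbance per % content), p x k
    pure <- vapply(cfg$components, function(comp) {
      Reduce(`+`, lapply(comp$bands, function(b)
        b$amplitude * exp(-0.5 * ((wn - b$center) / b$width)^2)))
    }, numeric(length(wn)))
    clean <- conc %*% t(pure)
    if (!is.null(cfg$background))
      clean <- sweep(clean, 2L, cfg$background(wn), `+`)
    gain <- stats::runif(n, cfg$scatter_gain_range[1],
                         cfg$scatter_gain_range[2])
    offset <- stats::runif(n, cfg$scatter_offset_range[1],
                           cfg$scatter_offset_range[2])
    t01 <- (wn[1] - wn) / (wn[1] - wn[length(wn)])
    basecoef <- matrix(stats::runif(3L * n, -1, 1), n, 3L) *
      cfg$baseline_amplitude
    baseline <- basecoef %*% rbind(rep(1, length(wn)), t01, t01^2)
    noise <- matrix(stats::rnorm(n * length(wn), 0, cfg$noise_sd),
                    n, length(wn))
    observed <- gain * (clean + baseline) + offset + noise
    spectra <- spectra_set(observed, wn, row_ids = ids)
    refs <- lapply(seq_len(k), function(j)
      reference_table(cfg$components[[j]]$name,
                      stats::setNames(conc[, j], ids)))
    names(refs) <- colnames(conc)
    list(spectra = spectra, references = refs,
         truth = list(concentrations = conc, clean = clean, gain = gain,
                      offset = offset, config = cfg))
  })
}

#' Write a simulated dataset to disk
#'
#' Emits the spectra as a wide CSV, all reference tables as one CSV, and
#' the generating ground truth (concentrations, per-sample gain/offset,
#' band layout) as JSON, into `dir`.
#'
#' @param sim a [simulate_nir()] result.
#' @param dir output directory (created if missing).
#' @return `invisible(dir)`.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_spectra_csv(sim$spectra, file.path(dir, "spectra.csv"))
  write_reference_csv(sim$references, file.path(dir, "references.csv"))
  cfg <- sim$truth$config
  truth <- list(
    concentrations = as.data.frame(sim$truth$concentrations),
    gain = sim$truth$gain, offset = sim$truth$offset,
    components = lapply(cfg$components, function(comp)
      list(name = comp$name,
           concentration_range = comp$concentration_range,
           bands = lapply(comp$bands, function(b)
             list(center = b$center, width = b$width,
                  amplitude = b$amplitude)))),
    grid = cfg$grid, noise_sd = cfg$noise_sd, seed = cfg$seed)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Ground-truth informative segments per component
#'
#' For each component, the set of segments whose wavenumber span overlaps
#' any of its bands' center +- 2.5 sd intervals — the segments a correct
#' wavelength-selection procedure should recover.
#'
#' @param cfg a [sim_config()].
#' @param scheme a [make_segments()] scheme for `cfg$grid[3]` variables.
#' @return named list of integer vectors (1-based segment indices).
#' @export
planted_segments <- function(cfg, scheme) {
  stopifnot(inherits(cfg, "sim_config"), inherits(scheme, "segment_scheme"))
  if (scheme$n_vars != cfg$grid[3])
    stop("scheme does not match the simulation grid", call. = FALSE)
  wn <- cfg$wavenumbers
  out <- lapply(cfg$components, function(comp) {
    segs <- integer(0)
    for (b in comp$bands) {
      lo <- b$center - 2.5 * b$width
      hi <- b$center + 2.5 * b$width
      for (d in seq_len(scheme$n_segments)) {
        i1 <- scheme$boundaries[d, "start"] + 1L
        i2 <- scheme$boundaries[d, "end"]
        seg_hi <- max(wn[i1], wn[i2]); seg_lo <- min(wn[i1], wn[i2])
        if (seg_lo <= hi && seg_hi >= lo) segs <- c(segs, d)
      }
    }
    sort(unique(segs))
  })
  names(out) <- vapply(cfg$components, `[[`, "", "name")
  out
}
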