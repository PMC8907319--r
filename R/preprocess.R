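#' Average replicate scans
#'
#' Collapses replicate scans to one spectrum per sample: each output row is
#' the arithmetic mean of the rows mapped to that sample by the spectra
#' set's `replicate_of` field. Output row order follows first appearance of
#' each sample group. Instruments typically acquire several scans per
#' sample; the averaged spectrum is then treated as the analytical spectrum
#' and pretreated (averaging happens before SNV, not after).
#'
#' @param s a [spectra_set()] with a non-NULL `replicate_of` map.
#' @return A [spectra_set()] with one row per sample id and no replicate map.
#' @export
average_replicates <- function(s) {
  stopifnot(inherits(s, "spectra_set"))
  if (is.null(s$replicate_of))
    stop("no replicate_of map on this spectra_set; skip averaging",
         call. = FALSE)
  groups <- unique(s$replicate_of)
  out <- matrix(0, length(groups), length(s$wavenumbers))
  for (g in seq_along(groups)) {
    rows <- which(s$replicate_of == groups[g])
    out[g, ] <- colMeans(s$absorbance[rows, , drop = FALSE])
  }
  spectra_set(out, s$wavenumbers, row_ids = groups)
}

#' Standard normal variate (SNV) transformation
#'
#' Autoscales each spectrum (row) to mean 0 and standard deviation 1:
#' \eqn{x' = (x - \bar{x}) / s_x}. SNV removes per-spectrum multiplicative
#' scatter (gain) and additive offset effects caused by particle size and
#' path-length variation, which is why it is the standard pretreatment for
#' diffuse-reflectance NIR of powders. The output is exactly invariant
#' under \eqn{x \mapsto a x + b} for any \eqn{a > 0}.
#'
#' @param s a [spectra_set()] or a numeric matrix (rows = spectra).
#' @param ddof degrees-of-freedom correction for the row standard
#'   deviation: 1 (default, sample sd with the n-1 denominator) or 0
#'   (population sd).
#' @return Object of the same type as `s`, row-standardized.
#' @examples
#' snv(matrix(c(1, 2, 3), 1))  # -1 0 1
#' @export
snv <- function(s, ddof = 1) {
  stopifnot(ddof %in% c(0, 1))
  x <- if (inherits(s, "spectra_set")) s$absorbance else as.matrix(s)
  if (ncol(x) < 2L)
    stop("SNV needs at least 2 variables per spectrum", call. = FALSE)
  mu <- rowMeans(x)
  cen <- x - mu
  sd2 <- rowSums(cen^2) / (ncol(x) - ddof)
  if (any(sd2 <= 0))
    stop("SNV undefined for constant spectrum row(s): ",
         paste(which(sd2 <= 0), collapse = ", "), call. = FALSE)
  out <- cen / sqrt(sd2)
  if (inherits(s, "spectra_set")) {
    spectra_set(out, s$wavenumbers, row_ids = s$row_ids,
                replicate_of = s$replicate_of)
  } else out
}
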