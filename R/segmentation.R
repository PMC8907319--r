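#' Partition the wavenumber axis into contiguous segments
#'
#' Splits `n_vars` spectral variables into `n_segments` contiguous blocks:
#' the first `n_segments - 1` segments all have width
#' `floor(n_vars / n_segments)` and the last segment absorbs the remainder.
#' For the full-resolution grid of 6539 variables and 21 segments this
#' gives twenty segments of width 311 and a final segment of width 319.
#' The segment scheme is the search space of the binary PSO: one bit per
#' segment.
#'
#' @param n_vars number of spectral variables (columns).
#' @param n_segments number of segments, `1 <= n_segments <= n_vars`.
#' @return An object of class `segment_scheme`: list with `n_vars`,
#'   `n_segments`, and `boundaries`, an `n_segments x 2` matrix of
#'   half-open `[start, end)` 0-based index pairs.
#' @examples
#' sc <- make_segments(6539, 21)
#' table(segment_widths(sc))
#' @export
make_segments <- function(n_vars, n_segments = 21L) {
  n_vars <- as.integer(n_vars); n_segments <- as.integer(n_segments)
  if (n_segments < 1L || n_vars < n_segments)
    stop("need n_vars >= n_segments >= 1", call. = FALSE)
  w <- n_vars %/% n_segments
  starts <- (seq_len(n_segments) - 1L) * w
  ends <- starts + w
  ends[n_segments] <- n_vars  # last segment takes the remainder
  structure(list(n_vars = n_vars, n_segments = n_segments,
                 boundaries = cbind(start = starts, end = ends)),
            class = "segment_scheme")
}

#' Segment widths of a scheme
#' @param scheme a [make_segments()] result.
#' @return integer vector of widths, one per segment.
#' @export
segment_widths <- function(scheme) {
  stopifnot(inherits(scheme, "segment_scheme"))
  as.integer(scheme$boundaries[, "end"] - scheme$boundaries[, "start"])
}

#' @export
print.segment_scheme <- function(x, ...) {
  w <- segment_widths(x)
  cat(sprintf("segment_scheme: %d variables in %d segments (widths %s)\n",
              x$n_vars, x$n_segments,
              paste(unique(w), collapse = "/")))
  invisible(x)
}

#' Expand a segment bitmask to variable indices
#'
#' @param mask 0/1 vector of length `scheme$n_segments`.
#' @param scheme a [make_segments()] result.
#' @return sorted integer vector of 1-based column indices covered by the
#'   selected segments (empty for the all-zeros mask).
#' @export
mask_to_variables <- function(mask, scheme) {
  stopifnot(inherits(scheme, "segment_scheme"))
  if (length(mask) != scheme$n_segments)
    stop("mask length must equal n_segments", call. = FALSE)
  on <- which(mask != 0)
  if (length(on) == 0L) return(integer(0))
  idx <- unlist(lapply(on, function(d)
    seq.int(scheme$boundaries[d, "start"] + 1L, scheme$boundaries[d, "end"])))
  sort(idx)
}

#' Selected wavenumber ranges of a bitmask
#'
#' Merges maximal runs of adjacent selected segments and reports each run
#' as an inclusive physical wavenumber range `(low, high)` in cm^-1, taken
#' from the grid values at the run's end points. This is the report format
#' used for selected-band tables.
#'
#' @param mask 0/1 vector of length `scheme$n_segments`.
#' @param scheme a [make_segments()] result.
#' @param wavenumbers numeric grid of length `scheme$n_vars`.
#' @return data.frame with columns `low`, `high` (cm^-1), one row per
#'   merged range, ordered by descending `high` (grid order).
#' @export
segments_to_wavenumber_ranges <- function(mask, scheme, wavenumbers) {
  stopifnot(inherits(scheme, "segment_scheme"))
  if (length(mask) != scheme$n_segments)
    stop("mask length must equal n_segments", call. = FALSE)
  if (length(wavenumbers) != scheme$n_vars)
    stop("wavenumbers length must equal scheme$n_vars", call. = FALSE)
  on <- mask != 0
  if (!any(on)) return(data.frame(low = numeric(0), high = numeric(0)))
  r <- rle(as.logical(on))
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  runs <- which(r$values)
  lo <- hi <- numeric(length(runs))
  for (k in seq_along(runs)) {
    seg_first <- starts[runs[k]]
    seg_last <- stops[runs[k]]
    i1 <- scheme$boundaries[seg_first, "start"] + 1L
    i2 <- scheme$boundaries[seg_last, "end"]
    wv <- wavenumbers[c(i1, i2)]
    lo[k] <- min(wv); hi[k] <- max(wv)
  }
  data.frame(low = lo, high = hi)
}

#' Write a selected-range table as CSV
#'
#' One row per component with its merged selected wavenumber ranges
#' rendered as "low-high" strings, the usual presentation of interval
#' selection results.
#'
#' @param ranges named list of data.frames from
#'   [segments_to_wavenumber_ranges()], one per component.
#' @param path output CSV path.
#' @return `invisible(path)`.
#' @export
write_selected_ranges_csv <- function(ranges, path) {
  rows <- vapply(names(ranges), function(comp) {
    rr <- ranges[[comp]]
    paste(sprintf("%.0f-%.0f", rr$low, rr$high), collapse = ", ")
  }, character(1))
  df <- data.frame(component = names(ranges), wavenumber_ranges = rows)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
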