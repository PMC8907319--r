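#' Spectra container
#'
#' A `spectra_set` holds an absorbance matrix on a shared wavenumber grid.
#' Rows are samples (or replicate scans), columns are wavenumbers in
#' reciprocal centimetres. The canonical wavenumber direction is descending
#' (10,000 down to 4,000 cm^-1), the usual NIR reporting convention;
#' constructors accept either direction and normalize.
#'
#' @param absorbance numeric matrix, one row per sample/scan.
#' @param wavenumbers numeric vector of length `ncol(absorbance)`, strictly
#'   monotone in either direction.
#' @param row_ids character vector of unique row identifiers; defaults to
#'   the matrix rownames or `"S1"`, `"S2"`, ...
#' @param replicate_of optional named character vector mapping each row id
#'   to the sample id whose replicate scan it is. Used by
#'   [average_replicates()].
#' @return An object of class `spectra_set` with fields `wavenumbers`,
#'   `absorbance`, `row_ids`, `replicate_of`.
#' @examples
#' s <- spectra_set(matrix(rnorm(15), 3), wavenumbers = c(9000, 8000, 7000,
#'   6000, 5000))
#' dim(s$absorbance)
#' @export
spectra_set <- function(absorbance, wavenumbers, row_ids = NULL,
                        replicate_of = NULL) {
  absorbance <- as.matrix(absorbance)
  storage.mode(absorbance) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) != ncol(absorbance))
    stop("length(wavenumbers) must equal ncol(absorbance)", call. = FALSE)
  if (is.null(row_ids)) {
    row_ids <- rownames(absorbance)
    if (is.null(row_ids)) row_ids <- paste0("S", seq_len(nrow(absorbance)))
  }
  row_ids <- as.character(row_ids)
  if (length(row_ids) != nrow(absorbance))
    stop("length(row_ids) must equal nrow(absorbance)", call. = FALSE)
  if (anyDuplicated(row_ids))
    stop("row_ids must be unique; duplicated: ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "),
         call. = FALSE)
  if (nrow(absorbance) > 0 && !all(is.finite(absorbance)))
    stop("absorbance values must all be finite", call. = FALSE)
  if (length(wavenumbers) >= 2) {
    d <- diff(wavenumbers)
    if (all(d > 0)) {
      # ascending input: normalize to canonical descending direction
      wavenumbers <- rev(wavenumbers)
      absorbance <- absorbance[, rev(seq_along(wavenumbers)), drop = FALSE]
    } else if (!all(d < 0)) {
      stop("wavenumbers must be strictly monotone", call. = FALSE)
    }
  }
  rownames(absorbance) <- row_ids
  colnames(absorbance) <- NULL
  if (!is.null(replicate_of)) {
    replicate_of <- as.character(replicate_of)[match(row_ids, names(replicate_of))]
    names(replicate_of) <- row_ids
    if (anyNA(replicate_of))
      stop("replicate_of must name every row id", call. = FALSE)
  }
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 row_ids = row_ids, replicate_of = replicate_of),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d spectra x %d wavenumbers (%.1f-%.1f cm-1)\n",
              nrow(x$absorbance), length(x$wavenumbers),
              if (length(x$wavenumbers)) max(x$wavenumbers) else NA,
              if (length(x$wavenumbers)) min(x$wavenumbers) else NA))
  if (!is.null(x$replicate_of))
    cat(sprintf("  replicate map over %d samples\n",
                length(unique(x$replicate_of))))
  invisible(x)
}

#' Reference-value table for one component
#'
#' Per-sample measured content (%) of a single named component, the
#' regression target of a calibration.
#'
#' @param component component name, e.g. `"moisture"`, `"caffeine"`,
#'   `"tea_polyphenols"`, `"tea_polysaccharides"`.
#' @param values named numeric vector, names are sample ids, values are
#'   contents in percent (finite, non-negative).
#' @return An object of class `reference_table`.
#' @export
reference_table <- function(component, values) {
  values <- unlist(values)
  if (is.null(names(values)) || any(names(values) == ""))
    stop("values must be named by sample id", call. = FALSE)
  if (anyDuplicated(names(values)))
    stop("sample ids must be unique", call. = FALSE)
  storage.mode(values) <- "double"
  if (length(values) && (!all(is.finite(values)) || any(values < 0)))
    stop("reference values must be finite and >= 0", call. = FALSE)
  structure(list(component = as.character(component)[1], values = values),
            class = "reference_table")
}

#' @export
print.reference_table <- function(x, ...) {
  cat(sprintf("reference_table: %s, %d samples", x$component,
              length(x$values)))
  if (length(x$values))
    cat(sprintf(", range %.4g-%.4g%%", min(x$values), max(x$values)))
  cat("\n")
  invisible(x)
}

#' Read a wide spectra CSV
#'
#' Expects a header row of numeric wavenumbers, a first column named
#' `sample_id` holding row identifiers, and one numeric absorbance column
#' per wavenumber. Wavenumbers may run in either direction; the returned
#' object is normalized to the canonical descending order.
#'
#' @param path path to a CSV file.
#' @return A validated [spectra_set()].
#' @export
read_spectra_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- strsplit(readLines(path, n = 1L), ",", fixed = TRUE)[[1]]
  if (length(header) < 2L || header[1] != "sample_id")
    stop("spectra CSV must start with a 'sample_id' column", call. = FALSE)
  wn <- suppressWarnings(as.numeric(header[-1]))
  if (anyNA(wn))
    stop("malformed wavenumber in header column(s) ",
         paste(which(is.na(wn)) + 1L, collapse = ", "), call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  mat <- suppressWarnings(
    matrix(as.numeric(as.matrix(df[, -1, drop = FALSE])),
           nrow = nrow(df), ncol = length(wn)))
  if (nrow(mat) > 0 && anyNA(mat)) {
    bad <- which(is.na(mat), arr.ind = TRUE)[1, ]
    stop(sprintf("malformed number at row %d (sample '%s'), column %d",
                 bad[1], df[[1]][bad[1]], bad[2] + 1L), call. = FALSE)
  }
  spectra_set(mat, wavenumbers = wn, row_ids = df[[1]])
}

#' Write a spectra CSV
#'
#' Inverse of [read_spectra_csv()]. Values are written with 17 significant
#' digits so a write/read round trip is stable to better than 1e-12.
#'
#' @param s a [spectra_set()].
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_spectra_csv <- function(s, path) {
  stopifnot(inherits(s, "spectra_set"))
  header <- paste(c("sample_id", format(s$wavenumbers, digits = 17,
                                        scientific = FALSE, trim = TRUE)),
                  collapse = ",")
  rows <- character(nrow(s$absorbance))
  for (i in seq_len(nrow(s$absorbance))) {
    rows[i] <- paste(c(s$row_ids[i],
                       formatC(s$absorbance[i, ], digits = 17, format = "g")),
                     collapse = ",")
  }
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read one component from a reference CSV
#'
#' The file must have a `sample_id` column and one numeric column per
#' measured component.
#'
#' @param path path to a CSV file.
#' @param component name of the column to load.
#' @return A [reference_table()] for the requested component.
#' @export
read_reference_csv <- function(path, component) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE,
                        colClasses = "character")
  if (!"sample_id" %in% names(df))
    stop("reference CSV must have a 'sample_id' column", call. = FALSE)
  if (!component %in% names(df))
    stop("component '", component, "' not found; available: ",
         paste(setdiff(names(df), "sample_id"), collapse = ", "),
         call. = FALSE)
  vals <- suppressWarnings(as.numeric(df[[component]]))
  if (anyNA(vals))
    stop("non-numeric value for component '", component, "' at row ",
         which(is.na(vals))[1], call. = FALSE)
  names(vals) <- df$sample_id
  reference_table(component, vals)
}

#' Write a reference CSV for one or more components
#'
#' @param tables a [reference_table()] or list of them sharing sample ids.
#' @param path output path.
#' @return `invisible(path)`.
#' @export
write_reference_csv <- function(tables, path) {
  if (inherits(tables, "reference_table")) tables <- list(tables)
  ids <- names(tables[[1]]$values)
  df <- data.frame(sample_id = ids, check.names = FALSE)
  for (tb in tables) {
    stopifnot(identical(names(tb$values), ids))
    df[[tb$component]] <- formatC(tb$values, digits = 17, format = "g")
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align spectra and reference values on shared sample ids
#'
#' Restricts both inputs to the intersection of their sample ids, in a
#' common order (spectra order). Idempotent.
#'
#' @param s a [spectra_set()].
#' @param r a [reference_table()].
#' @return list with elements `spectra` and `reference`.
#' @export
align_spectra <- function(s, r) {
  stopifnot(inherits(s, "spectra_set"), inherits(r, "reference_table"))
  common <- s$row_ids[s$row_ids %in% names(r$values)]
  if (length(common) == 0L)
    stop("no shared sample ids between spectra and reference table",
         call. = FALSE)
  keep <- match(common, s$row_ids)
  s2 <- spectra_set(s$absorbance[keep, , drop = FALSE], s$wavenumbers,
                    row_ids = common,
                    replicate_of = if (is.null(s$replicate_of)) NULL
                                   else s$replicate_of[keep])
  r2 <- reference_table(r$component, r$values[common])
  list(spectra = s2, reference = r2)
}
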