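#' Raman spectrum object
#'
#' One wavenumber/intensity trace plus sample metadata (cell line,
#' methionine level, insulin level, cell id, droplet id, and any further
#' fields). Wavenumbers must be strictly increasing and intensities finite.
#'
#' @param wavenumber Numeric, strictly increasing (cm^-1).
#' @param intensity Numeric, same length, finite.
#' @param metadata Named list of sample annotations.
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumber, intensity, metadata = list()) {
  wavenumber <- as.numeric(wavenumber)
  intensity <- as.numeric(intensity)
  if (length(wavenumber) != length(intensity))
    stop("wavenumber and intensity lengths differ")
  if (length(wavenumber) == 0L) stop("empty spectrum")
  if (any(!is.finite(wavenumber)) || any(!is.finite(intensity)))
    stop("non-finite values in spectrum")
  if (any(diff(wavenumber) <= 0))
    stop("wavenumbers must be strictly increasing (no duplicates)")
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 metadata = as.list(metadata)),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %d points, %.0f-%.0f cm^-1\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber)))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata),
                             vapply(x$metadata, function(v) paste(format(v), collapse = ","), ""),
                             sep = "=", collapse = "; "), "\n")
  invisible(x)
}

#' @export
length.raman_spectrum <- function(x) length(x$wavenumber)

#' Read a two-column spectrum table
#'
#' Reads a TSV/CSV with wavenumber in the first column and intensity in the
#' second (header optional). Descending grids are sorted ascending with a
#' warning; non-numeric data rows and duplicated wavenumbers are rejected.
#'
#' @param path File path.
#' @param metadata Named list attached to the returned spectrum.
#' @return A [raman_spectrum()].
#' @export
read_spectrum_table <- function(path, metadata = list()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty spectrum file: ", path)
  sep <- if (grepl(",", lines[[length(lines)]], fixed = TRUE)) "," else ""
  split_row <- function(s) {
    if (sep == ",") strsplit(s, ",", fixed = TRUE)[[1]]
    else strsplit(trimws(s), "[[:space:]]+")[[1]]
  }
  first <- suppressWarnings(as.numeric(split_row(lines[[1]])))
  start <- if (any(is.na(first))) 2L else 1L  # header row
  if (start > length(lines)) stop("no data rows in ", path)
  rows <- lapply(seq(start, length(lines)), function(i) {
    v <- suppressWarnings(as.numeric(split_row(lines[[i]])))
    if (length(v) < 2L || any(is.na(v[1:2])))
      stop(sprintf("non-numeric data in %s at line %d", path, i))
    v[1:2]
  })
  m <- do.call(rbind, rows)
  if (anyDuplicated(m[, 1]))
    stop("duplicate wavenumbers in ", path)
  if (is.unsorted(m[, 1])) {
    warning("wavenumbers not ascending in ", path, "; sorting")
    m <- m[order(m[, 1]), , drop = FALSE]
  }
  raman_spectrum(m[, 1], m[, 2], metadata)
}

#' Write a spectrum as a two-column table
#'
#' @param spectrum A [raman_spectrum()].
#' @param path Output file path.
#' @param sep Column separator, `"\t"` (default) or `","`.
#' @return `path`, invisibly.
#' @export
write_spectrum_table <- function(spectrum, path, sep = "\t") {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  utils::write.table(
    data.frame(wavenumber = format(spectrum$wavenumber, digits = 17),
               intensity = format(spectrum$intensity, digits = 17)),
    path, sep = sep, quote = FALSE, row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Labelled spectrum collection
#'
#' A set of spectra sharing one wavenumber grid, with factor labels drawn
#' from their metadata. This is the grouped container used by averaging,
#' entropy ranking, ratio statistics and classification.
#'
#' @param spectra List of [raman_spectrum()] objects on an identical grid.
#' @return An object of class `spectrum_set` with elements `wavenumber`
#'   (shared grid), `intensity` (spectra x wavenumber matrix) and `meta`
#'   (data.frame, one row per spectrum).
#' @export
spectrum_set <- function(spectra) {
  stopifnot(length(spectra) >= 1L,
            all(vapply(spectra, inherits, TRUE, "raman_spectrum")))
  grid <- spectra[[1]]$wavenumber
  same <- vapply(spectra, function(s)
    length(s$wavenumber) == length(grid) && all(s$wavenumber == grid), TRUE)
  if (!all(same)) stop("all spectra must share an identical wavenumber grid")
  ints <- do.call(rbind, lapply(spectra, `[[`, "intensity"))
  keys <- unique(unlist(lapply(spectra, function(s) names(s$metadata))))
  meta <- if (length(keys)) {
    as.data.frame(lapply(stats::setNames(keys, keys), function(k)
      vapply(spectra, function(s) {
        v <- s$metadata[[k]]
        if (is.null(v)) NA_character_
        else paste(as.character(v), collapse = ";")
      }, "")), stringsAsFactors = FALSE)
  } else data.frame(row.names = seq_along(spectra))
  structure(list(wavenumber = grid, intensity = ints, meta = meta),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d spectra x %d wavenumbers (%.0f-%.0f cm^-1)\n",
              nrow(x$intensity), ncol(x$intensity),
              min(x$wavenumber), max(x$wavenumber)))
  if (ncol(x$meta)) cat("  factors:", paste(names(x$meta), collapse = ", "), "\n")
  invisible(x)
}

#' Number of spectra in a set
#' @param set A [spectrum_set()].
#' @return Integer count.
#' @export
n_spectra <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  nrow(set$intensity)
}

#' Factor labels of a spectrum set
#'
#' @param set A [spectrum_set()].
#' @param factor_name Metadata column name (e.g. `"methionine_x"`).
#' @return Factor of labels, one per spectrum.
#' @export
set_labels <- function(set, factor_name) {
  stopifnot(inherits(set, "spectrum_set"))
  if (!factor_name %in% names(set$meta))
    stop("unknown factor: ", factor_name)
  factor(set$meta[[factor_name]])
}

#' Extract one spectrum from a set
#' @param set A [spectrum_set()].
#' @param i Spectrum index.
#' @return A [raman_spectrum()].
#' @export
set_spectrum <- function(set, i) {
  stopifnot(inherits(set, "spectrum_set"), i >= 1, i <= nrow(set$intensity))
  raman_spectrum(set$wavenumber, set$intensity[i, ],
                 as.list(set$meta[i, , drop = FALSE]))
}
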