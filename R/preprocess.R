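#' Subtract a paired background spectrum
#'
#' Per-droplet background correction: the background trace, acquired at the
#' same focal plane as the droplet, is subtracted pointwise. Negative
#' residual intensities are retained (not clipped) so downstream noise
#' statistics stay unbiased; simplex normalization handles them explicitly.
#'
#' @param spectrum,background [raman_spectrum()] objects on identical grids.
#' @return A [raman_spectrum()]; metadata of `spectrum` is preserved and
#'   `preprocessing` gains a `"background_subtracted"` entry.
#' @export
subtract_background <- function(spectrum, background) {
  stopifnot(inherits(spectrum, "raman_spectrum"),
            inherits(background, "raman_spectrum"))
  if (length(spectrum$wavenumber) != length(background$wavenumber) ||
      any(spectrum$wavenumber != background$wavenumber))
    stop("spectrum and background grids differ")
  out <- raman_spectrum(spectrum$wavenumber,
                        spectrum$intensity - background$intensity,
                        spectrum$metadata)
  out$metadata$preprocessing <- c(spectrum$metadata$preprocessing,
                                  "background_subtracted")
  out
}

#' Normalize a spectrum
#'
#' Three normalizations used for lipid-droplet spectra:
#' \describe{
#'   \item{`vector`}{divide by the Euclidean norm so \eqn{\|I\|_2 = 1}.}
#'   \item{`simplex`}{closure to sum one, \eqn{\sum I = 1}. If negative
#'     intensities are present (e.g. after background subtraction) the
#'     minimum is first shifted to zero, with a warning; the shift is
#'     recorded in the metadata.}
#'   \item{`peak`}{divide by the peak intensity at `at` cm^-1, taken as the
#'     maximum within `window` cm^-1 of `at` (robust to 1-2 cm^-1
#'     calibration jitter). Used for ratiometric analyses, conventionally at
#'     the 2940 cm^-1 protein peak.}
#' }
#' Each method is idempotent.
#'
#' @param spectrum A [raman_spectrum()].
#' @param method `"vector"`, `"simplex"` or `"peak"`.
#' @param at Target wavenumber for `method = "peak"` (default 2940).
#' @param window Half-width (cm^-1) of the peak search window (default 5).
#' @return Normalized [raman_spectrum()]; the method applied is appended to
#'   `metadata$preprocessing`.
#' @export
normalize_spectrum <- function(spectrum, method = c("vector", "simplex", "peak"),
                               at = 2940, window = 5) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  method <- match.arg(method)
  I <- spectrum$intensity
  meta <- spectrum$metadata
  if (method == "vector") {
    nrm <- sqrt(sum(I^2))
    if (nrm == 0) stop("all-zero spectrum cannot be vector-normalized")
    I <- I / nrm
  } else if (method == "simplex") {
    if (any(I < 0)) {
      warning("negative intensities; shifting minimum to zero before closure")
      meta$simplex_shift <- -min(I)
      I <- I - min(I)
    }
    s <- sum(I)
    if (s == 0) stop("all-zero spectrum cannot be simplex-normalized")
    I <- I / s
  } else {
    pk <- peak_intensity(spectrum, at, window = window)
    if (!is.finite(pk) || pk <= 0)
      stop(sprintf("peak intensity at %g cm^-1 is not positive", at))
    I <- I / pk
    meta$peak_norm_at <- at
  }
  out <- raman_spectrum(spectrum$wavenumber, I, meta)
  out$metadata$preprocessing <- c(meta$preprocessing, paste0("normalize_", method))
  out
}

#' Peak intensity by windowed maximum
#'
#' The intensity assigned to a named band: the maximum intensity within
#' `window` cm^-1 of the target wavenumber. A windowed maximum rather than a
#' single grid point tolerates small calibration jitter.
#'
#' @param spectrum A [raman_spectrum()].
#' @param at Target wavenumber (cm^-1); must lie inside the grid.
#' @param window Half-width of the search window (cm^-1).
#' @return Scalar intensity.
#' @export
peak_intensity <- function(spectrum, at, window = 5) {
  stopifnot(inherits(spectrum, "raman_spectrum"), length(at) == 1L)
  w <- spectrum$wavenumber
  if (at < min(w) || at > max(w))
    stop(sprintf("band %g cm^-1 lies outside the spectral grid [%g, %g]",
                 at, min(w), max(w)))
  sel <- abs(w - at) <= window
  if (!any(sel)) sel <- which.min(abs(w - at))  # coarse grid fallback
  max(spectrum$intensity[sel])
}

#' Group-averaged spectra with dispersion bands
#'
#' Mean and sample standard deviation per wavenumber for each level
#' combination of the grouping factor(s), as drawn as shaded one-SD bands
#' around group-average traces.
#'
#' @param set A [spectrum_set()].
#' @param factors Character vector of metadata columns to group by.
#' @return A data.frame with columns `group`, the factor columns,
#'   `wavenumber`, `mean`, `sd`, `n`. For singleton groups `sd` is `NA`
#'   (flagged, not an error).
#' @export
group_average <- function(set, factors) {
  stopifnot(inherits(set, "spectrum_set"), length(factors) >= 1L)
  miss <- setdiff(factors, names(set$meta))
  if (length(miss)) stop("unknown factor(s): ", paste(miss, collapse = ", "))
  key <- interaction(set$meta[factors], drop = TRUE, sep = "/")
  out <- lapply(levels(key), function(lv) {
    rows <- which(key == lv)
    m <- colMeans(set$intensity[rows, , drop = FALSE])
    s <- if (length(rows) >= 2L) apply(set$intensity[rows, , drop = FALSE], 2, stats::sd)
         else rep(NA_real_, ncol(set$intensity))
    lab <- set$meta[rows[1], factors, drop = FALSE]
    cbind(data.frame(group = lv, row.names = NULL),
          lab[rep(1, length(m)), , drop = FALSE],
          data.frame(wavenumber = set$wavenumber, mean = m, sd = s,
                     n = length(rows), row.names = NULL))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Apply the standard preprocessing chain to every spectrum in a set
#'
#' Convenience wrapper: optional paired-background subtraction, then the
#' configured normalization sequence (default vector then simplex, the
#' chain used for clustering and entropy inputs). The chain actually applied
#' is recorded in each spectrum's metadata.
#'
#' @param set A [spectrum_set()].
#' @param methods Character vector of [normalize_spectrum()] methods applied
#'   in order.
#' @param backgrounds Optional list of background [raman_spectrum()]s, one
#'   per spectrum.
#' @return A new [spectrum_set()].
#' @export
preprocess_set <- function(set, methods = c("vector", "simplex"),
                           backgrounds = NULL) {
  stopifnot(inherits(set, "spectrum_set"))
  spectra <- lapply(seq_len(n_spectra(set)), function(i) {
    s <- set_spectrum(set, i)
    if (!is.null(backgrounds)) s <- subtract_background(s, backgrounds[[i]])
    for (m in methods) s <- normalize_spectrum(s, m)
    s
  })
  spectrum_set(spectra)
}
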