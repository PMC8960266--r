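#' Synthesize one lipid-droplet Raman spectrum
#'
#' Sum of pseudo-Voigt bands on a regular wavenumber grid plus iid additive
#' Gaussian noise (homoscedastic across wavenumbers). The default grid spans
#' 600-3200 cm^-1 at 1 cm^-1 steps, covering the fingerprint, cell-silent
#' and C-H stretching regions.
#'
#' @param bands Band table (data.frame with `center`, `fwhm`, `amplitude`,
#'   `mixing`), a list of [band_spec()], or `NULL`/empty for a flat spectrum.
#' @param grid Ascending numeric wavenumber grid (cm^-1).
#' @param noise_sd Standard deviation of the additive noise (>= 0).
#' @param seed Optional integer seed; fixed seed gives identical output.
#' @param metadata Metadata list attached to the spectrum.
#' @return A [raman_spectrum()].
#' @export
generate_ld_spectrum <- function(bands = ld_reference_bands(),
                                 grid = seq(600, 3200, by = 1),
                                 noise_sd = 0, seed = NULL,
                                 metadata = list()) {
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  I <- numeric(length(grid))
  if (!is.null(bands) && NROW(bands) > 0) {
    bt <- as_band_table(bands)
    for (i in seq_len(nrow(bt)))
      I <- I + pseudo_voigt(grid, bt$center[i], bt$amplitude[i],
                            bt$fwhm[i], bt$mixing[i])
  }
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    I <- I + stats::rnorm(length(grid), 0, noise_sd)
  }
  raman_spectrum(grid, I, metadata)
}

#' Cohort design for synthetic spectra
#'
#' Describes a factorial study: factor levels (cell line x methionine x
#' insulin), per-group band-amplitude multipliers, replication, and noise.
#' Defaults mirror the study layout: 2 methionine levels crossed with 3
#' insulin levels, 5 cells per group and 5 droplet spectra per cell.
#'
#' @param cell_lines Character vector of cell-line levels.
#' @param methionine_x Numeric methionine levels (multiples of physiological).
#' @param insulin_x Numeric insulin levels (multiples of physiological).
#' @param cells_per_group Cells per factor-level combination (>= 1).
#' @param spectra_per_cell Droplet spectra per cell (>= 1).
#' @param noise_sd Additive noise SD (intensity units, >= 0).
#' @param multipliers Named list: for selected groups, a named numeric
#'   vector of amplitude multipliers keyed by band rowname (see
#'   [ld_reference_bands()]). Group keys are
#'   `"<cell_line>|met<methionine_x>|ins<insulin_x>"`; missing entries mean
#'   multiplier 1 (no effect).
#' @param bands Baseline band table.
#' @param grid Wavenumber grid.
#' @param seed Integer seed for the whole cohort.
#' @return An object of class `cohort_design` (a list).
#' @export
cohort_design <- function(cell_lines = "MDA-MB-231",
                          methionine_x = c(1, 20),
                          insulin_x = c(0.1, 1, 2),
                          cells_per_group = 5,
                          spectra_per_cell = 5,
                          noise_sd = 0.02,
                          multipliers = list(),
                          bands = ld_reference_bands(),
                          grid = seq(600, 3200, by = 1),
                          seed = 1L) {
  if (cells_per_group < 1) stop("cells_per_group must be >= 1")
  if (spectra_per_cell < 1) stop("spectra_per_cell must be >= 1")
  if (!is.finite(noise_sd) || noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(cell_lines = cell_lines, methionine_x = methionine_x,
                 insulin_x = insulin_x, cells_per_group = cells_per_group,
                 spectra_per_cell = spectra_per_cell, noise_sd = noise_sd,
                 multipliers = multipliers, bands = as_band_table(bands),
                 grid = grid, seed = as.integer(seed)),
            class = "cohort_design")
}

group_key <- function(cell_line, met, ins)
  sprintf("%s|met%g|ins%g", cell_line, met, ins)

#' Generate a labelled spectrum cohort with known ground truth
#'
#' Emulates the factorial study design: for every cell line x methionine x
#' insulin group, `cells_per_group` cells each contribute
#' `spectra_per_cell` droplet spectra whose band amplitudes are the baseline
#' amplitudes times the group's multipliers, plus additive Gaussian noise.
#' Every spectrum carries full factor metadata; the returned `truth` table
#' records the per-group expected amplitude of each band.
#'
#' @param design A [cohort_design()].
#' @return A list with elements `set` (a [spectrum_set()]) and `truth`
#'   (data.frame: group, band, center, expected amplitude).
#' @export
generate_spectrum_cohort <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  bands <- design$bands
  band_names <- rownames(bands)
  if (is.null(band_names)) band_names <- as.character(bands$center)
  spectra <- list()
  truth <- list()
  cell_counter <- 0L
  for (cl in design$cell_lines) for (met in design$methionine_x)
    for (ins in design$insulin_x) {
      key <- group_key(cl, met, ins)
      mult <- rep(1, nrow(bands))
      names(mult) <- band_names
      gm <- design$multipliers[[key]]
      if (!is.null(gm)) {
        unknown <- setdiff(names(gm), band_names)
        if (length(unknown))
          stop("multiplier names not in band table: ",
               paste(unknown, collapse = ", "))
        mult[names(gm)] <- gm
      }
      gb <- bands
      gb$amplitude <- gb$amplitude * mult
      truth[[key]] <- data.frame(group = key, cell_line = cl,
                                 methionine_x = met, insulin_x = ins,
                                 band = band_names, center = bands$center,
                                 amplitude = gb$amplitude,
                                 row.names = NULL)
      for (cell in seq_len(design$cells_per_group)) {
        cell_counter <- cell_counter + 1L
        for (ld in seq_len(design$spectra_per_cell)) {
          spectra[[length(spectra) + 1L]] <- generate_ld_spectrum(
            gb, design$grid, design$noise_sd, seed = NULL,
            metadata = list(cell_line = cl, methionine_x = met,
                            insulin_x = ins, cell_id = cell_counter,
                            droplet_id = ld, group = key))
        }
      }
    }
  list(set = spectrum_set(spectra), truth = do.call(rbind, truth))
}
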