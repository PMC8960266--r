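#' Pseudo-Voigt (Gaussian-Lorentzian blend) line shape
#'
#' Evaluates a single vibrational band as a height-parameterized blend of a
#' Gaussian and a Lorentzian sharing one centre and one full width at half
#' maximum (FWHM):
#' \deqn{I(\nu) = h\,[\eta\,L(\nu) + (1-\eta)\,G(\nu)]}
#' where both \eqn{L} and \eqn{G} have unit height at the centre, so the
#' profile peaks at exactly `height` for any mixing fraction.
#'
#' @param nu Numeric vector of wavenumbers (cm^-1) at which to evaluate.
#' @param center Band centre (cm^-1).
#' @param height Peak height at the centre (intensity units, >= 0).
#' @param fwhm Full width at half maximum (cm^-1, > 0), shared by the
#'   Gaussian and Lorentzian parts.
#' @param mixing Lorentzian fraction \eqn{\eta} in \[0, 1\]; 0 is a pure
#'   Gaussian, 1 a pure Lorentzian.
#' @return Numeric vector of intensities, same length as `nu`.
#' @examples
#' nu <- seq(2800, 2900, by = 0.5)
#' I <- pseudo_voigt(nu, center = 2850, height = 1, fwhm = 20, mixing = 0.3)
#' max(I)  # 1 at the centre
#' @export
pseudo_voigt <- function(nu, center, height, fwhm, mixing = 0) {
  stopifnot(is.numeric(nu), length(center) == 1L, length(fwhm) == 1L)
  if (!is.finite(fwhm) || fwhm <= 0) stop("`fwhm` must be > 0")
  if (!is.finite(height) || height < 0) stop("`height` must be >= 0")
  if (!is.finite(mixing) || mixing < 0 || mixing > 1)
    stop("`mixing` must lie in [0, 1]")
  d2 <- (nu - center)^2
  g <- exp(-4 * log(2) * d2 / fwhm^2)
  l <- 1 / (1 + 4 * d2 / fwhm^2)
  height * (mixing * l + (1 - mixing) * g)
}

#' Band specification
#'
#' A single Raman band for the synthetic spectrum generator: a pseudo-Voigt
#' component parameterized by peak height (not area), so normalization
#' contracts downstream stay simple.
#'
#' @param center Band centre (cm^-1).
#' @param fwhm Full width at half maximum (cm^-1, > 0).
#' @param amplitude Peak height (>= 0).
#' @param mixing Lorentzian fraction in \[0, 1\].
#' @return An object of class `band_spec` (a named list).
#' @export
band_spec <- function(center, fwhm, amplitude, mixing = 0) {
  if (!is.finite(fwhm) || fwhm <= 0) stop("`fwhm` must be > 0")
  if (!is.finite(amplitude) || amplitude < 0) stop("`amplitude` must be >= 0")
  if (!is.finite(mixing) || mixing < 0 || mixing > 1)
    stop("`mixing` must lie in [0, 1]")
  structure(list(center = center, fwhm = fwhm, amplitude = amplitude,
                 mixing = mixing),
            class = "band_spec")
}

#' Reference lipid-droplet band table
#'
#' Default band set used by the synthetic generator, covering the bands a
#' deuterium-probed lipid-droplet spectrum exhibits: fingerprint protein
#' bands (phenylalanine 1000, amide III 1200-1300, amide II' 1450, heme
#' 1558, aromatic side chains 1610, amide I 1660 cm^-1), the carbon-deuterium
#' doublet in the cell-silent region (2135 lipid, 2180 protein cm^-1), and
#' the C-H stretching region (2850 CH2, 2880 Fermi CH2, 2935 CH3,
#' 3010 =C-H cm^-1).
#'
#' @return A data.frame with columns `center`, `fwhm`, `amplitude`, `mixing`
#'   and rownames naming each band.
#' @export
ld_reference_bands <- function() {
  b <- data.frame(
    center    = c(1000, 1250, 1450, 1558, 1610, 1660,
                  2135, 2180, 2850, 2880, 2935, 3010),
    fwhm      = c(10, 60, 30, 20, 15, 30, 40, 40, 30, 35, 35, 25),
    amplitude = c(0.20, 0.25, 0.45, 0.12, 0.10, 0.35,
                  0.30, 0.25, 1.00, 0.70, 0.80, 0.25),
    mixing    = rep(0.3, 12)
  )
  rownames(b) <- c("phe_1000", "amide3_1250", "amide2p_1450", "heme_1558",
                   "aromatic_1610", "amide1_1660", "cd_lipid_2135",
                   "cd_protein_2180", "ch2_2850", "ch2_fermi_2880",
                   "ch3_2935", "unsat_3010")
  b
}

# coerce a band table / list of band_spec into a plain data.frame
as_band_table <- function(bands) {
  if (is.data.frame(bands)) {
    stopifnot(all(c("center", "fwhm", "amplitude") %in% names(bands)))
    if (is.null(bands$mixing)) bands$mixing <- 0
    return(bands)
  }
  if (inherits(bands, "band_spec")) bands <- list(bands)
  do.call(rbind, lapply(bands, function(b) {
    data.frame(center = b$center, fwhm = b$fwhm, amplitude = b$amplitude,
               mixing = b$mixing)
  }))
}
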