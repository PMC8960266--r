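# closed-form KL divergence between two univariate Gaussians (nats)
gaussian_kl_closed <- function(m1, s1, m2, s2) {
  log(s2 / s1) + (s1^2 + (m1 - m2)^2) / (2 * s2^2) - 0.5
}

# shared support spanning both Gaussians' mass (mirrors the package default)
pair_support <- function(m1, s1, m2, s2, k = 6) {
  c(min(m1, m2) - k * max(s1, s2), max(m1, m2) + k * max(s1, s2))
}

# cohort with one band's amplitude scaled in the second methionine group
shifted_cohort <- function(band, multiplier, seed, noise_sd = 0.02,
                           cells_per_group = 5, spectra_per_cell = 5,
                           insulin_x = 1) {
  m <- list()
  m[["X|met20|ins1"]] <- stats::setNames(multiplier, band)
  generate_spectrum_cohort(cohort_design(
    cell_lines = "X", methionine_x = c(1, 20), insulin_x = insulin_x,
    cells_per_group = cells_per_group, spectra_per_cell = spectra_per_cell,
    noise_sd = noise_sd, multipliers = m, seed = seed))
}

# four well-separated pseudo-Voigt components on the amide window
four_peak_truth <- function() {
  list(band_spec(1445, 18, 0.8, 0.3), band_spec(1558, 16, 0.3, 0.5),
       band_spec(1610, 14, 0.25, 0.2), band_spec(1660, 22, 0.9, 0.4))
}
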