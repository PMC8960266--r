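# ramanld

Chemometric and morphometric analysis of lipid-droplet (LD) metabolism from
spontaneous Raman spectra and SRS/TPF microscopy, for studies that probe
*de novo* synthesis with heavy water (D2O): deuterium incorporated into newly
built molecules creates C-D bands (~2135 cm^-1 for lipids, ~2180 cm^-1 for
proteins) in the cell-silent spectral region, so band ratios against the C-H
stretches (2850 CH2 lipid, 2935 CH3 protein, 2880 Fermi CH2, 3010 =C-H)
report lipogenesis, protein synthesis, lipid arrangement and saturation at
subcellular resolution. The package is aimed at spectroscopists and cell
biologists comparing cell phenotypes under crossed nutrient manipulations
(e.g. methionine × insulin) who need the full analysis chain validated
against ground truth.

## What it computes

* **Preprocessing** — per-droplet background subtraction; vector, simplex
  (sum-to-one) and protein-peak (2940 cm^-1) normalization; group-average
  spectra with SD bands.
* **Relative-entropy feature ranking** — per-wavenumber class Gaussians are
  discretized into probability vectors and scored by Kullback–Leibler
  divergence: cross entropy
  H(A,B) = −Σᵢ p_A(νᵢ) log p_B(νᵢ),
  D_KL(A‖B) = Σᵢ p_A log(p_A/p_B),
  its symmetrized mean, and for k ≥ 3 classes the average divergence
  D(P₁…P_k) = [1/(k(k−1))] Σᵢ Σⱼ D_KL(Pᵢ‖Pⱼ),
  yielding a profile that ranks every Raman shift by its power to
  discriminate treatment groups.
* **Pseudo-Voigt unmixing** — multi-peak Gaussian-Lorentzian blend fits
  h·[ηL + (1−η)G] with bounded Levenberg–Marquardt, fit-error % and R²,
  plus topographic peak prominence and width at half prominence.
* **Ratiometric statistics** — CH₂:CH₃, CD_L:CD_P, CD_L:CH₂, 2850:2880
  arrangement indicator and 3010 unsaturation intensity; quadrature-
  propagated ratio differences; balanced two-way ANOVA with sum-to-zero
  constraints; two-tailed t-tests (Welch default).
* **Classification & embedding** — a 100-unit rectifier (ReLU) MLP with
  softmax output, cross-entropy + L2 (α = 2e-4) loss and full-batch Adam
  updates W_{i+1} = W_i − ε∇Loss(W_i); PCA (top 10 components) followed by
  exact t-SNE at perplexity 30 with no exaggeration.
* **Imaging** — stripe-artifact removal and 3D Gaussian smoothing; Otsu
  thresholding and 26-connected 3D droplet segmentation; radial-dispersion
  sphericity scoring max(0, 1 − SD(r)/mean(r)) with filtering; per-cell
  count/volume summaries; rolling-ball (default radius 50 px) and
  sliding-paraboloid background subtraction; optical redox ratio
  F/(F+N); line profiles, per-cell intensity histograms with SEM, and
  maximum-intensity projections. TIFF I/O throughout.
* **Synthetic data** — labelled spectra cohorts (pseudo-Voigt bands +
  Gaussian noise, factorial designs with known per-group effects) and image
  phantoms (droplet stacks with stripes and noise, flavin/NADH pairs with
  smooth background), all with exact ground truth for validation.

## Worked example

Simulate the 2 × 3 methionine × insulin design with an insulin-graded
boost of the 2135 cm^-1 C-D lipid band in the excess-methionine groups
(an interaction by construction), then test it and rank wavenumbers:

```r
library(ramanld)

design <- cohort_design(
  cell_lines = "MDA-MB-231",
  methionine_x = c(1, 20), insulin_x = c(0.1, 1, 2),
  cells_per_group = 5, spectra_per_cell = 5, noise_sd = 0.02,
  multipliers = list(
    "MDA-MB-231|met20|ins0.1" = c(cd_lipid_2135 = 1.1),
    "MDA-MB-231|met20|ins1"   = c(cd_lipid_2135 = 1.4),
    "MDA-MB-231|met20|ins2"   = c(cd_lipid_2135 = 1.8)),
  seed = 42)
cohort <- generate_spectrum_cohort(design)
cohort$set
#> <spectrum_set> 150 spectra x 2601 wavenumbers (600-3200 cm^-1)
#>   factors: cell_line, methionine_x, insulin_x, cell_id, droplet_id, group

ratios <- compute_ratios(cohort$set)
anova2_balanced(ratios$cdl_ch2, ratios$methionine_x, ratios$insulin_x,
                names = c("methionine", "insulin"))
#>                 term  df sum_sq  mean_sq    F         p
#> 1         methionine   1  0.476 0.475881 3613 7.00e-104
#> 2            insulin   2  0.206 0.102892  781  4.95e-78
#> 3 methionine:insulin   2  0.198 0.099031  752  6.13e-77
#> 4              error 144  0.019 0.000132   NA        NA

prof <- entropy_profile(suppressWarnings(preprocess_set(cohort$set)),
                        "methionine_x", L = 1e4)
head(prof$top, 3)
#>   wavenumber    score
#> 1       2135 14.10473
#> 2       2133 12.44375
#> 3       2137 12.03767
```

The ANOVA recovers the injected structure — methionine, insulin and their
interaction all load on the CD_L:CH₂ *de novo* lipogenesis ratio — and the
entropy profile ranks the 2135 cm^-1 band (and its immediate neighbours)
as the most discriminating wavenumbers, exactly where the effect was
planted. The warnings suppressed around `preprocess_set()` are the
documented simplex-shift notices for noise-negative intensities.

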