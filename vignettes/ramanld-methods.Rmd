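---
title: "Methods: lipid-droplet Raman chemometrics and morphometry with ramanld"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lipid-droplet Raman chemometrics and morphometry with ramanld}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanld)
```

# Scope and data model

`ramanld` quantifies lipid-droplet (LD) metabolism from two kinds of data:
labelled spontaneous Raman spectra of single droplets, and microscopy images
— 3D stimulated Raman scattering (SRS) stacks acquired at the 2850 cm^-1
lipid band and 2D two-photon autofluorescence (flavin/NADH) image pairs.
The driving application is the comparison of breast-cell phenotypes (a
triple-negative line against a normal-like control) under crossed
methionine × insulin nutrient manipulation with heavy-water (D2O) probing,
where deuterium incorporated into newly synthesized molecules creates C-D
bands near 2135 (lipid) and 2180 cm^-1 (protein) in the otherwise silent
spectral region.

Because the original spectra and images are not publicly deposited, the
package ships a first-class synthetic-data module whose outputs carry full
ground truth. Every downstream stage is validated against that truth or
against closed-form oracles, never against the generator's own code paths.

A `raman_spectrum` is one wavenumber/intensity trace plus metadata (cell
line, methionine level, insulin level, cell id, droplet id); a
`spectrum_set` is a collection on one shared grid with factor accessors.
Image stacks are plain numeric arrays ordered (y, x, z) with 1-based voxel
coordinates — rows, columns, TIFF pages.

# Synthetic data: what it emulates, and what it does not

`generate_ld_spectrum()` builds a spectrum as a sum of pseudo-Voigt bands
plus iid additive Gaussian noise, on a default grid of 600–3200 cm^-1 at
1 cm^-1 (the acquisition grid of the original instrument is not published;
the default spans the fingerprint, cell-silent and C-H regions and is a
config choice). Bands are parameterized by *peak height*, not area, because
the analyses report peak intensities; `ld_reference_bands()` collects the
twelve bands the application names (1000, 1200–1300, 1450, 1558, 1610,
1660, 2135, 2180, 2850, 2880, 2935, 3010 cm^-1) with plausible widths and
relative heights.

`generate_spectrum_cohort()` replicates the factorial study layout — by
default 5 droplet spectra per cell and 5 cells per group, the replication
the study states — applying per-group band-amplitude multipliers so group
effects are known exactly. Noise is homoscedastic across wavenumbers, the
simplest model consistent with the published dispersion bands. The default
noise SD of 0.02 (2% of the unit CH2 peak) is a realistic droplet-spectrum
signal-to-noise choice and is fixed once here, not tuned per analysis.

Image phantoms paint spheres/ellipsoids of unit intensity over a 0.1
background (`generate_droplet_stack()`), add the horizontal scan-stripe
artifact as an additive per-row sinusoid plus offset with per-slice phase
(a concrete, removable stand-in for laser-scanning noise), then iid
Gaussian noise; droplet surfaces keep a 4-voxel clearance so smoothing at
the scales used cannot merge neighbours. `generate_fluorescence_pair()`
paints disk cells with per-cell channel levels over a planar background
ramp — the structure rolling-ball subtraction is designed to remove.
`morphology_scenario()` encodes the reported morphology contrast (excess
methionine: fewer but larger droplets) as two groups with jittered per-cell
counts (~12 droplets of radius 5.5–7.5 voxels vs ~6 of 7.5–9.5).

Deliberate non-goals: no optical point-spread function, no shot-noise
statistics, no multiplicative scattering effects, no deuterium kinetics
over time. Passing tests therefore demonstrate correctness of the
*computations*, not robustness to every artifact of real acquisitions.

# Spectral preprocessing

Per-droplet background subtraction is a pointwise difference against a
background trace taken at the same focal plane (`subtract_background()`);
negative residuals are retained to keep noise statistics unbiased. Three
normalizations are provided (`normalize_spectrum()`): vector (unit
Euclidean norm), simplex (closure to sum one; negative values are first
shifted to zero with a warning and the shift recorded in metadata — the
sum-to-one reading of "simplex normalization" is a documented
interpretation), and peak normalization at 2940 cm^-1 for ratiometric work.
The default chain for clustering and entropy inputs is background →
vector → simplex; the chain applied is logged in each spectrum's metadata.
All normalizations are idempotent and never touch labels.

Peak intensity at a named band is the maximum within ±5 cm^-1 of the
nominal position, tolerant to 1–2 cm^-1 calibration jitter.

# Relative-entropy ranking of wavenumbers

At each wavenumber, each class's intensities are summarized by a Gaussian
(sample mean, Bessel-corrected SD floored at 1e-6 × the global intensity
range — degenerate classes would otherwise give infinite divergences). The
class densities are discretized on a shared support spanning all class
means ±6 class SDs (capturing all but ~1e-9 of the mass) into probability
vectors of length L, floored at 1e-300 and renormalized. Divergences:
cross entropy \(H(A,B) = -\sum_i p_A(v_i)\log p_B(v_i)\), Kullback–Leibler
\(D_{KL}(A\|B) = \sum_i p_A \log(p_A/p_B)\), the symmetrized form
\((D_{KL}(A\|B)+D_{KL}(B\|A))/2\), and for k ≥ 3 classes the average
divergence \(\frac{1}{k(k-1)}\sum_i\sum_j D_{KL}(P_i\|P_j)\), which reduces
exactly to the symmetrized form at k = 2.

The routine default is L = 1e5: the discretized symmetric KL already
agrees with the closed-form Gaussian divergence to well under 1% there,
so the reference setting of 1e7 bins is supported but not forced (it costs
100× the memory and time for no numerical benefit at reporting precision).
`entropy_profile()` scores every wavenumber for one grouping factor —
methionine (k = 2) and insulin (k = 3) are ranked separately; the
interaction is not entropy-ranked. With class parameters *estimated* from
n spectra per class, the null divergence does not vanish: it floors at
O(1/n) per wavenumber, and its maximum over a ~2600-point grid is a few
tenths of a nat at n = 50/class. A genuine 2-SD band shift scores about
2 nats, an order of magnitude above that floor; the localization tests are
framed accordingly.

# Pseudo-Voigt peak unmixing

A band is modelled as \(h[\eta L(\nu) + (1-\eta)G(\nu)]\) with the Gaussian
and Lorentzian sharing one centre and FWHM and each unit-height at the
centre — the common Gaussian-Lorentzian blend parameterization (the source
analyses name the blend but no functional form). `unmix_peaks()` fits a sum
of such components inside a window by bounded Levenberg–Marquardt
(minpack.lm), centres constrained to the window, FWHM positive, η in
[0, 1]. Auto-initialization places starts at the most prominent local
maxima of a lightly smoothed (5-point binomial) copy, greedily enforcing a
5 cm^-1 minimum separation so twin noise maxima on one peak top never claim
two components; width starts at the width at half prominence and η at 0.5.

Fit error is reported as 100·Σ|residual|/Σ|data| over the window (the
published fit-error percentages come with no definition; an RMS-based
variant is returned alongside so both conventions are available), plus
R² = 1 − SS_res/SS_tot and a convergence flag. The published example
values (2.367%/0.98854 and 2.620%/0.98544) additionally depend on the
unreleased averaged spectra and are treated as context, not reproduction
targets. `peak_shape_metrics()` computes standard topographic prominence
and the width at the half-prominence crossing with linear interpolation;
both are invariant to constant baselines.

# Ratiometric statistics

`compute_ratios()` extracts I(2135), I(2180), I(2850), I(2880), I(2935),
I(3010) by the windowed-maximum rule and forms CH2:CH3 (lipid:protein),
CD_L:CD_P (de novo lipid : de novo protein), CD_L:CH2 (de novo : total
lipid), the 2850:2880 lipid-arrangement indicator, and the 3010
unsaturation intensity. A zero numerator yields ratio 0 (no label); a
non-positive denominator yields NA with a flag, never a dropped row.
Group-difference uncertainties propagate in quadrature
(`ratio_contrast()`).

`anova2_balanced()` is the classical fixed-effects two-factor ANOVA for
fully balanced designs with sum-to-zero constraints — the setting where
Type I/II/III sums of squares coincide, which is how "constrained sum of
squares" is read here. It is computed via `stats::aov` with `contr.sum`
and verified in tests against hand-computed textbook sums of squares.
Unbalanced designs are rejected rather than approximated, and n = 1 per
cell is rejected (interaction inestimable). Each spectrum is treated as a
datum (measurements pooled across trials, as in the source analyses);
aggregating to cell means before testing is a caller-side choice of input.
`t_test_two_tailed()` defaults to the Welch form (unequal variances are
plausible across treatment groups); the pooled form is a flag away.

For the power analysis, "a one-error-SD interaction effect" is injected as
the crossed sum-to-zero pattern g = (+1, 0, −1; −1, 0, +1) scaled by one
error SD — the natural reading of an interaction *contrast* of that size.
(A single-cell bump of one SD gives noncentrality 25/3 at n = 25 and only
~0.73 power, so the bump reading cannot be the intended 80%-power design.)

# Classification and embedding

`train_spectrum_classifier()` implements the stated architecture directly:
one hidden layer of 100 rectified units, softmax output, cross-entropy
loss with L2 penalty α = 2e-4, trained by full-batch Adam (adaptive-moment
first-order updates of the subtracted-gradient form) for at most 200
iterations, on spectra range-normalized to [0, 1]. The learning rate is
not published; the Adam default of 1e-3 is used. Evaluation is a seeded
stratified 80/20 split. The implementation is in-package because no
installed R package offers this exact architecture/update rule
(`nnet` is logistic/BFGS); its behaviour is validated behaviourally —
chance accuracy on null cohorts, high accuracy on separable ones,
monotonicity in class separation, weight shrinkage under heavy L2.

`embed_pca_tsne()` projects spectra onto the top 10 principal components
(variance-ranked; explained variance reported non-increasing) and embeds
them with exact O(n²) t-SNE at perplexity 30 and early-exaggeration factor
1 — "no exaggeration" read literally. Exact t-SNE is implemented
in-package (no t-SNE package is available in the supported stack) and is
adequate at cohort scale (tens to a few hundred spectra). Initialization
is from the first two PCs scaled small, making the pipeline deterministic
given the seed; exact duplicate spectra are collapsed before embedding and
share coordinates, since a deterministic map must send identical inputs to
identical outputs.

# Imaging

De-striping (`destripe_and_smooth()`) estimates each slice's stripe
component as the per-row *median* (robust to sparse bright droplets),
high-passes it along the row axis with a 15-voxel running mean so genuine
smooth background variation survives, subtracts it row-wise, then applies
separable 3D Gaussian smoothing (default SD 0.8 voxel). A frequency-domain
notch at zero fast-scan frequency was considered and rejected: it also
removes the row-mean contribution of genuine droplets, so a stripe-free
image would not pass through unchanged.

Segmentation thresholds at Otsu's value (or a fixed override), groups
voxels by 26-connectivity (connected components of the voxel adjacency
graph via igraph) and discards components under 27 voxels. Volumes are
reported in voxels and µm³. Sphericity is the radial-dispersion score
max(0, 1 − SD(r)/mean(r)) over centroid-to-surface-voxel distances
(surface = voxels with an exposed 6-neighbour face); the underlying idea —
dispersion of Euclidean distances from the centre of mass to the surface —
is stated in the source, the coefficient-of-variation form is this
package's concrete choice. An ideal sphere scores 1; voxelized spheres of
radius ≥ 6 score ≥ 0.9; elongation strictly lowers the score. The default
retention threshold is 0.6, a config choice (no value is published).
Single-voxel droplets score 1 by convention and are flagged.

Rolling-ball background subtraction is grayscale opening with a non-flat
ball surface; for radii ≥ 16 px the image is min-pooled to a coarser grid,
the ball rolled there, and the background bilinearly interpolated back —
the standard acceleration for this filter, with min-pooling keeping the
estimate under the intensity surface. The sliding paraboloid is applied as
separable 1D parabolic erosion/dilation passes along rows then columns.
Backgrounds are clamped at the image, so the subtraction is non-negative
wherever the input sits on or above its background. The redox map is
F/(F+N) where the denominator is positive (NA elsewhere), bounded in
[0, 1], with per-cell means over labelled masks; cell masks come from the
synthetic truth or the user (the original cell segmentation was manual).
Line profiles are bilinear, histograms are per-cell relative frequencies
with across-cell SEM per bin, and maximum-intensity projections are
per-pixel maxima along z.

# Numerical choices and degenerate inputs

* Probability floors: p ≥ 1e-300 before renormalization; σ ≥ 1e-6 × global
  intensity range. Both perturb divergences below reporting precision.
* Discretization: L ≥ 1000 enforced; below that, binning error dominates.
* All-zero spectra cannot be normalized (error); constant ANOVA responses
  return all-zero sums of squares with F = 0/0 (NaN) and a degenerate flag;
  empty segmentations return empty lists, and cells with no retained
  droplets report count 0 with NA volume, never silent drops.
* Every generator takes a seed and is bit-reproducible; downstream
  stochastic steps (splits, initializations) are seeded through their
  configs.

# Problem sizes

The validation suite runs at desk scale, chosen as the package's own test
design: cohorts of 25–100 spectra per class on 1–2 cm^-1 grids, probability
vectors of length 1e3–1e5 (1e5 for oracle comparisons), 64³ phantom stacks
with 1–10 droplets, 192² fluorescence images, 2000-replicate null and
500-replicate power simulations for the ANOVA, and 10-seed batteries for
classifier and localization checks.

# Known limitations

Entropy scores are unsigned (no direction of change); densities other than
Gaussian are not fitted; the unmixer does not select the number of peaks;
true Voigt (convolution) profiles are not implemented; no mixed-effects or
repeated-measures models; no droplet–mitochondria co-localization; no
isosurface rendering or deconvolution. Published headline numbers that
depend on the unreleased raw data (specific fit-error percentages, bar
values, p-values, the "ten-fold" ratio-difference increase) are context
for the methods, not quantities this package claims to reproduce.
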