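#' Named peak ratios per spectrum
#'
#' Extracts the band intensities used in the ratiometric metabolism
#' analysis and forms the named ratios:
#' \describe{
#'   \item{`ch2_ch3`}{I(2850)/I(2935) — total lipid : protein.}
#'   \item{`cdl_cdp`}{I(2135)/I(2180) — de novo lipid : de novo protein.}
#'   \item{`cdl_ch2`}{I(2135)/I(2850) — de novo lipid : total lipid.}
#'   \item{`arrangement`}{I(2850)/I(2880) — lipid-arrangement indicator,
#'     inversely related to acyl-chain lattice order.}
#'   \item{`unsat`}{I(3010) — unsaturated-lipid intensity.}
#' }
#' Band intensities use the windowed-maximum rule of [peak_intensity()].
#' A zero numerator gives ratio 0 (no deuterium label); a non-positive
#' denominator gives `NA` with the `flag` column set (never silently
#' dropped).
#'
#' @param set A [spectrum_set()].
#' @param peaks Named numeric vector of band positions (cm^-1); defaults to
#'   the C-H, C-D and unsaturation bands.
#' @param window Half-width of the peak search window (cm^-1).
#' @return data.frame: one row per spectrum with metadata columns, raw band
#'   intensities (`I2850`, ...), the ratios, and `flag`.
#' @export
compute_ratios <- function(set,
                           peaks = c(ch2 = 2850, ch2_fermi = 2880,
                                     ch3 = 2935, cd_l = 2135, cd_p = 2180,
                                     unsat = 3010),
                           window = 5) {
  stopifnot(inherits(set, "spectrum_set"))
  rng <- range(set$wavenumber)
  bad <- peaks < rng[1] | peaks > rng[2]
  if (any(bad))
    stop("band(s) outside the spectral grid: ",
         paste(sprintf("%s (%g)", names(peaks)[bad], peaks[bad]), collapse = ", "))
  n <- n_spectra(set)
  I <- vapply(seq_len(n), function(i) {
    s <- set_spectrum(set, i)
    vapply(peaks, function(p) peak_intensity(s, p, window), 0)
  }, numeric(length(peaks)))
  I <- t(I)  # spectra x peaks
  colnames(I) <- paste0("I", peaks)
  safe_ratio <- function(num, den) {
    r <- ifelse(num == 0, 0, ifelse(den > 0, num / den, NA_real_))
    r
  }
  out <- data.frame(set$meta, I,
                    ch2_ch3 = safe_ratio(I[, "I2850"], I[, "I2935"]),
                    cdl_cdp = safe_ratio(I[, "I2135"], I[, "I2180"]),
                    cdl_ch2 = safe_ratio(I[, "I2135"], I[, "I2850"]),
                    arrangement = safe_ratio(I[, "I2850"], I[, "I2880"]),
                    unsat = I[, "I3010"],
                    check.names = FALSE)
  out$flag <- apply(out[c("ch2_ch3", "cdl_cdp", "cdl_ch2", "arrangement")], 1,
                    function(r) any(is.na(r)))
  rownames(out) <- NULL
  out
}

#' Group ratio difference with quadrature-propagated SD
#'
#' Difference of two group means with its uncertainty propagated in
#' quadrature: \eqn{SD = \sqrt{SD_X^2 + SD_Y^2}}.
#'
#' @param mean_x,sd_x Mean and SD of group X.
#' @param mean_y,sd_y Mean and SD of group Y.
#' @return List with `difference` and `sd` (`sd` is `NA` with a warning if
#'   either input SD is missing).
#' @export
ratio_contrast <- function(mean_x, sd_x, mean_y, sd_y) {
  d <- mean_x - mean_y
  if (is.na(sd_x) || is.na(sd_y)) {
    warning("missing group SD; propagated SD undefined")
    return(list(difference = d, sd = NA_real_))
  }
  list(difference = d, sd = sqrt(sd_x^2 + sd_y^2))
}

#' Balanced two-way ANOVA with sum-to-zero constraints
#'
#' Classical fixed-effects two-factor analysis of variance for a fully
#' balanced design (equal replication in every cell), with sum-to-zero
#' effect constraints — the setting in which Type I/II/III sums of squares
#' coincide. Fitted via [stats::aov()] with `contr.sum` contrasts.
#' Unbalanced designs and designs with one observation per cell (interaction
#' inestimable) are rejected.
#'
#' @param values Numeric response vector.
#' @param factor_a,factor_b Factor labels (coerced with [factor()]).
#' @param names Optional length-2 character, term names for the two factors.
#' @return Object of class `anova_table`: data.frame with rows for factor A,
#'   factor B, the A:B interaction and error; columns `term`, `df`,
#'   `sum_sq`, `mean_sq`, `F`, `p`. If the response is constant all SS are
#'   0, F is reported `NaN` (0/0) and the attribute `degenerate` is `TRUE`.
#' @export
anova2_balanced <- function(values, factor_a, factor_b,
                            names = c("A", "B")) {
  a <- factor(factor_a); b <- factor(factor_b)
  stopifnot(length(values) == length(a), length(values) == length(b))
  if (anyNA(values)) stop("missing values in response")
  counts <- table(a, b)
  if (length(unique(as.vector(counts))) != 1L)
    stop("design is unbalanced; balanced two-way ANOVA requires equal cell counts")
  if (counts[1] < 2L)
    stop("one observation per cell: interaction term inestimable")
  fit <- stats::aov(values ~ a * b,
                    contrasts = list(a = "contr.sum", b = "contr.sum"))
  s <- summary(fit)[[1]]
  ss <- s[["Sum Sq"]]; df <- s[["Df"]]
  degenerate <- stats::var(values) == 0
  if (degenerate) ss <- rep(0, length(ss))  # constant response: exact zeros
  ms <- ss / df
  Fv <- ms[1:3] / ms[4]  # 0/0 = NaN when degenerate
  p <- stats::pf(Fv, df[1:3], df[4], lower.tail = FALSE)
  out <- data.frame(
    term = c(names[1], names[2], paste0(names[1], ":", names[2]), "error"),
    df = df, sum_sq = ss, mean_sq = ms,
    F = c(Fv, NA), p = c(p, NA))
  rownames(out) <- NULL
  class(out) <- c("anova_table", "data.frame")
  attr(out, "degenerate") <- degenerate
  out
}

#' Two-tailed two-sample t-test
#'
#' Thin wrapper over [stats::t.test()] reporting the two-tailed statistic,
#' degrees of freedom and p-value. Welch's unequal-variance form is the
#' default; the pooled-variance form is available via `var_equal = TRUE`.
#'
#' @param x,y Numeric samples (each n >= 2).
#' @param var_equal Use the pooled-variance statistic.
#' @return List with `t`, `df`, `p`.
#' @export
t_test_two_tailed <- function(x, y, var_equal = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("each sample needs n >= 2")
  if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y))
    return(list(t = 0, df = length(x) + length(y) - 2, p = 1))
  ht <- stats::t.test(x, y, alternative = "two.sided", var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Significance annotation for figure captions
#'
#' Maps a p-value to the star/octothorp levels used in the figure
#' annotations: thresholds 0.05, 0.01, 0.001, 0.0001.
#'
#' @param p Numeric p-value(s).
#' @param symbol Character used for the marks (default `"*"`).
#' @return Character vector: `""`, `"*"`, `"**"`, `"***"` or `"****"`.
#' @export
significance_marks <- function(p, symbol = "*") {
  n <- findInterval(-log10(pmax(p, .Machine$double.xmin)),
                    -log10(c(0.05, 0.01, 0.001, 0.0001)))
  vapply(n, function(k) paste(rep(symbol, k), collapse = ""), "")
}
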