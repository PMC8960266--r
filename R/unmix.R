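# sum of pseudo-Voigt components; par = c(center, height, fwhm, eta) x n
pv_sum <- function(nu, par) {
  n <- length(par) / 4
  I <- numeric(length(nu))
  for (i in seq_len(n)) {
    p <- par[(4 * i - 3):(4 * i)]
    I <- I + pseudo_voigt(nu, p[1], p[2], p[3], p[4])
  }
  I
}

#' Multi-peak pseudo-Voigt unmixing of a spectral window
#'
#' Decomposes the intensities inside `window` into `n_peaks` pseudo-Voigt
#' components by bounded Levenberg-Marquardt least squares
#' ([minpack.lm::nls.lm]). Centres are constrained to the window, widths to
#' be positive, mixing fractions to \[0, 1\]. Initialization is either a
#' supplied component list or automatic (the `n_peaks` most prominent local
#' maxima after light smoothing; width from the width at half prominence,
#' mixing 0.5).
#'
#' Reported fit quality: `error_pct` = 100 * sum(|residual|) / sum(|data|)
#' (an RMS-based alternative, 100 * RMS(residual)/RMS(data), is returned
#' alongside), and `r_squared` = 1 - SS_res/SS_tot.
#'
#' @param spectrum A [raman_spectrum()].
#' @param window Length-2 numeric, wavenumber interval to fit.
#' @param n_peaks Number of components (>= 1).
#' @param init Optional list of [band_spec()]-like components (fields
#'   `center`, `amplitude` or `height`, `fwhm`, `mixing`) used as start
#'   values; `NULL` for auto-initialization.
#' @param max_iter Maximum optimizer iterations.
#' @return Object of class `unmix_result`: `components` (data.frame ordered
#'   by centre: center, height, fwhm, mixing), `wavenumber`, `data`,
#'   `fitted`, `error_pct`, `error_pct_rms`, `r_squared`, `converged`,
#'   `iterations`.
#' @export
unmix_peaks <- function(spectrum, window, n_peaks, init = NULL,
                        max_iter = 200) {
  stopifnot(inherits(spectrum, "raman_spectrum"),
            length(window) == 2L, n_peaks >= 1)
  window <- sort(window)
  sel <- spectrum$wavenumber >= window[1] & spectrum$wavenumber <= window[2]
  if (sum(sel) < 4 * n_peaks + 1)
    stop("window contains too few points for the requested number of peaks")
  nu <- spectrum$wavenumber[sel]
  y <- spectrum$intensity[sel]

  if (is.null(init)) {
    pk <- find_peaks(nu, y)
    # greedy pick by prominence, keeping starts at least 5 cm^-1 apart so
    # twin maxima on one noisy peak top never claim two components
    pk <- pk[order(pk$prominence, decreasing = TRUE), , drop = FALSE]
    chosen <- integer(0)
    for (r in seq_len(nrow(pk))) {
      if (length(chosen) == n_peaks) break
      if (!length(chosen) ||
          all(abs(pk$wavenumber[chosen] - pk$wavenumber[r]) >= 5))
        chosen <- c(chosen, r)
    }
    if (length(chosen) < n_peaks)
      stop(sprintf(paste("auto-initialization found only %d local maxima for",
                         "%d peaks; supply `init` with starting components"),
                   length(chosen), n_peaks))
    pk <- pk[chosen, ]
    start <- as.vector(t(cbind(pk$wavenumber, pk$height,
                               pmax(pk$width, 2 * min(diff(nu))), 0.5)))
  } else {
    if (length(init) != n_peaks) stop("`init` must supply n_peaks components")
    start <- unlist(lapply(init, function(b) {
      h <- if (!is.null(b$height)) b$height else b$amplitude
      c(b$center, h, b$fwhm, if (is.null(b$mixing)) 0.5 else b$mixing)
    }))
  }

  step <- min(diff(nu))
  lower <- rep(c(window[1], 0, step / 2, 0), n_peaks)
  upper <- rep(c(window[2], Inf, diff(window) * 2, 1), n_peaks)
  start <- pmin(pmax(start, lower + 1e-12), ifelse(is.finite(upper), upper - 1e-12, start))

  fit <- minpack.lm::nls.lm(par = start,
                            fn = function(p) y - pv_sum(nu, p),
                            lower = lower, upper = upper,
                            control = minpack.lm::nls.lm.control(
                              maxiter = max_iter, ptol = 1e-12, ftol = 1e-12))
  par <- fit$par
  comps <- data.frame(center = par[seq(1, length(par), 4)],
                      height = par[seq(2, length(par), 4)],
                      fwhm = par[seq(3, length(par), 4)],
                      mixing = par[seq(4, length(par), 4)])
  comps <- comps[order(comps$center), ]
  rownames(comps) <- NULL
  fitted <- pv_sum(nu, par)
  res <- y - fitted
  ss_tot <- sum((y - mean(y))^2)
  structure(list(components = comps, wavenumber = nu, data = y,
                 fitted = fitted,
                 error_pct = 100 * sum(abs(res)) / sum(abs(y)),
                 error_pct_rms = 100 * sqrt(mean(res^2) / mean(y^2)),
                 r_squared = 1 - sum(res^2) / ss_tot,
                 converged = fit$info %in% 1:4,
                 iterations = fit$niter),
            class = "unmix_result")
}

#' @export
print.unmix_result <- function(x, ...) {
  cat(sprintf("<unmix_result> %d components, error %.3f%%, R^2 %.5f%s\n",
              nrow(x$components), x$error_pct, x$r_squared,
              if (x$converged) "" else " (NOT converged)"))
  print(x$components, digits = 4)
  invisible(x)
}

# local maxima with topographic prominence and width at half prominence on a
# lightly smoothed copy (5-point binomial kernel) for initialization
# robustness
find_peaks <- function(nu, y, smooth = TRUE) {
  ys <- if (smooth && length(y) >= 7)
    stats::filter(y, c(1, 4, 6, 4, 1) / 16, sides = 2) else y
  ys[is.na(ys)] <- y[is.na(ys)]
  ys <- as.numeric(ys)
  n <- length(ys)
  idx <- which(diff(sign(diff(ys))) < 0) + 1L
  if (!length(idx))
    return(data.frame(wavenumber = numeric(), height = numeric(),
                      prominence = numeric(), width = numeric()))
  out <- lapply(idx, function(i) {
    m <- peak_prominence_width(nu, ys, i)
    data.frame(wavenumber = nu[i], height = y[i],
               prominence = m["prominence"], width = m["width"])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# topographic prominence of peak at index i and its width at half prominence
peak_prominence_width <- function(nu, y, i) {
  n <- length(y)
  h <- y[i]
  # walk left/right until a higher point; reference = min along each walk
  left_min <- h; j <- i
  while (j > 1) { j <- j - 1; if (y[j] > h) break; left_min <- min(left_min, y[j]) }
  hit_left <- j >= 1 && y[j] > h
  right_min <- h; j <- i
  while (j < n) { j <- j + 1; if (y[j] > h) break; right_min <- min(right_min, y[j]) }
  hit_right <- j <= n && y[j] > h
  ref <- if (hit_left && hit_right) max(left_min, right_min)
         else if (hit_left) right_min
         else if (hit_right) left_min
         else min(left_min, right_min)
  prom <- h - ref
  half <- h - prom / 2
  # linear interpolation to the half-prominence crossings
  xl <- nu[1]; j <- i
  while (j > 1 && y[j - 1] >= half) j <- j - 1
  if (j > 1) {
    f <- (half - y[j]) / (y[j - 1] - y[j])
    xl <- nu[j] + f * (nu[j - 1] - nu[j])
  } else xl <- nu[1]
  xr <- nu[n]; j <- i
  while (j < n && y[j + 1] >= half) j <- j + 1
  if (j < n) {
    f <- (half - y[j]) / (y[j + 1] - y[j])
    xr <- nu[j] + f * (nu[j + 1] - nu[j])
  } else xr <- nu[n]
  c(prominence = prom, width = xr - xl)
}

#' Peak prominence and width at half prominence
#'
#' Topographic peak metrics on a spectral region: prominence is the peak
#' height above the higher of the two flanking reference minima (walking
#' outward until a higher point or the region edge), and the width is
#' measured where the signal crosses peak height minus half the prominence,
#' with linear interpolation between grid points. Both are invariant to a
#' constant baseline.
#'
#' @param spectrum A [raman_spectrum()].
#' @param region Length-2 numeric wavenumber interval.
#' @param min_prominence Peaks with smaller prominence are dropped (default
#'   0, keep all).
#' @return data.frame with one row per local maximum: `wavenumber`,
#'   `height`, `prominence`, `width` (cm^-1), ordered by decreasing
#'   prominence. Zero rows if the region is flat.
#' @export
peak_shape_metrics <- function(spectrum, region, min_prominence = 0) {
  stopifnot(inherits(spectrum, "raman_spectrum"), length(region) == 2L)
  region <- sort(region)
  sel <- spectrum$wavenumber >= region[1] & spectrum$wavenumber <= region[2]
  if (sum(sel) < 3) stop("region contains fewer than 3 grid points")
  nu <- spectrum$wavenumber[sel]
  y <- spectrum$intensity[sel]
  pk <- find_peaks(nu, y, smooth = FALSE)
  pk <- pk[pk$prominence >= min_prominence, , drop = FALSE]
  pk[order(pk$prominence, decreasing = TRUE), , drop = FALSE]
}
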