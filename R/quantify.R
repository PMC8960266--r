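#' Optical redox ratio map
#'
#' Per-pixel ratio flavin / (flavin + NADH), defined where the denominator
#' is positive and `NA` elsewhere. With labelled cell masks, per-cell mean
#' ratios over each mask are also returned. Bounded in \[0, 1\] wherever
#' both channels are non-negative.
#'
#' @param flavin,nadh Aligned, background-subtracted images (matrices of
#'   identical shape).
#' @param masks Optional integer label matrix (0 = background).
#' @return List with `map` (matrix) and, when masks are given, `per_cell`
#'   (data.frame: cell, mean_ratio, n_pixels).
#' @export
redox_map <- function(flavin, nadh, masks = NULL) {
  if (!all(dim(flavin) == dim(nadh)))
    stop("flavin and nadh images differ in shape")
  tot <- flavin + nadh
  map <- ifelse(tot > 0, flavin / tot, NA_real_)
  out <- list(map = map)
  if (!is.null(masks)) {
    if (!all(dim(masks) == dim(flavin))) stop("masks shape mismatch")
    cells <- sort(unique(masks[masks > 0]))
    out$per_cell <- do.call(rbind, lapply(cells, function(cid) {
      v <- map[masks == cid]
      data.frame(cell = cid, mean_ratio = mean(v, na.rm = TRUE),
                 n_pixels = sum(masks == cid))
    }))
  }
  out
}

#' Intensity profile along a line segment
#'
#' Bilinearly interpolated intensities of one or more channels along the
#' segment from `p0` to `p1` (pixel coordinates, (y, x), 1-based).
#'
#' @param images A matrix or named list of matrices (channels).
#' @param p0,p1 Length-2 numeric endpoints (y, x).
#' @param n_points Number of sample points along the segment.
#' @return data.frame with `distance` (pixels from `p0`) and one column per
#'   channel.
#' @export
line_profile <- function(images, p0, p1, n_points = 200) {
  if (is.matrix(images)) images <- list(intensity = images)
  stopifnot(length(p0) == 2L, length(p1) == 2L)
  len <- sqrt(sum((p1 - p0)^2))
  if (len == 0) stop("zero-length line")
  t <- seq(0, 1, length.out = n_points)
  ys <- p0[1] + t * (p1[1] - p0[1])
  xs <- p0[2] + t * (p1[2] - p0[2])
  interp <- function(m) {
    y0 <- pmin(pmax(floor(ys), 1), nrow(m) - 1); fy <- ys - y0
    x0 <- pmin(pmax(floor(xs), 1), ncol(m) - 1); fx <- xs - x0
    m[cbind(y0, x0)] * (1 - fy) * (1 - fx) +
      m[cbind(y0 + 1, x0)] * fy * (1 - fx) +
      m[cbind(y0, x0 + 1)] * (1 - fy) * fx +
      m[cbind(y0 + 1, x0 + 1)] * fy * fx
  }
  out <- data.frame(distance = t * len)
  for (nm in names(images)) out[[nm]] <- interp(images[[nm]])
  out
}

#' Per-cell pixel-intensity histograms with across-cell SEM
#'
#' Bins the pixel intensities of each labelled cell into shared breaks and
#' reports per-cell relative frequencies plus, per bin, the across-cell mean
#' frequency and its standard error (the shaded-band summary used for
#' composite intensity histograms).
#'
#' @param image Numeric matrix.
#' @param masks Integer label matrix (0 = background).
#' @param breaks Number of bins or explicit break vector spanning the cell
#'   intensity range.
#' @return List with `per_cell` (matrix cells x bins of relative
#'   frequencies), `mid` (bin midpoints), `mean` and `sem` (per-bin across
#'   cells; `sem` is `NA` with a single cell).
#' @export
mask_histograms <- function(image, masks, breaks = 32) {
  stopifnot(all(dim(image) == dim(masks)))
  cells <- sort(unique(masks[masks > 0]))
  if (!length(cells)) stop("no labelled cells in masks")
  vals <- image[masks > 0]
  if (length(breaks) == 1L)
    breaks <- seq(min(vals), max(vals), length.out = breaks + 1L)
  per_cell <- t(vapply(cells, function(cid) {
    h <- graphics::hist(image[masks == cid], breaks = breaks, plot = FALSE,
                        include.lowest = TRUE)
    h$counts / sum(h$counts)
  }, numeric(length(breaks) - 1L)))
  rownames(per_cell) <- cells
  sem <- if (length(cells) > 1L)
    apply(per_cell, 2, stats::sd) / sqrt(length(cells))
  else rep(NA_real_, ncol(per_cell))
  list(per_cell = per_cell,
       mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
       mean = colMeans(per_cell), sem = sem)
}

#' Maximum-intensity projection of a stack
#'
#' @param stack Numeric array (y, x, z).
#' @return Matrix: per-pixel maximum along z.
#' @export
max_intensity_projection <- function(stack) {
  stopifnot(length(dim(stack)) == 3)
  apply(stack, c(1, 2), max)
}

#' Region quantification dispatcher
#'
#' Single entry point over the three region geometries: `"line"` calls
#' [line_profile()], `"masks"` calls [mask_histograms()], `"whole"` returns
#' the [max_intensity_projection()].
#'
#' @param x Image, image list, or stack as required by the geometry.
#' @param geometry `"line"`, `"masks"` or `"whole"`.
#' @param ... Passed to the underlying function.
#' @return See the respective function.
#' @export
region_quantify <- function(x, geometry = c("line", "masks", "whole"), ...) {
  geometry <- match.arg(geometry)
  switch(geometry,
         line = line_profile(x, ...),
         masks = mask_histograms(x, ...),
         whole = max_intensity_projection(x))
}

#' Read / write multi-page TIFF stacks
#'
#' Thin wrappers over the tiff package storing stacks as one page per z
#' slice, 32-bit float, preserving intensity values.
#'
#' @param path File path.
#' @param stack Numeric array (y, x, z) or matrix.
#' @return `read_image_stack` returns an array (y, x, z);
#'   `write_image_stack` returns `path` invisibly.
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (is.matrix(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (i in seq_along(pages)) arr[, , i] <- pages[[i]]
  arr
}

#' @rdname read_image_stack
#' @export
write_image_stack <- function(stack, path) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  pages <- lapply(seq_len(dim(stack)[3]), function(z) stack[, , z])
  tiff::writeTIFF(pages, path, bits.per.sample = 32, reduce = FALSE)
  invisible(path)
}
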