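# separable Gaussian smoothing along each array dimension, edge-replicated
gaussian_kernel <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  k / sum(k)
}

smooth_along_dim1 <- function(m, k) {
  # m: matrix, smooth each column; replicate-pad the edges
  half <- (length(k) - 1L) / 2L
  n <- nrow(m)
  mp <- rbind(m[rep(1L, half), , drop = FALSE], m,
              m[rep(n, half), , drop = FALSE])
  out <- stats::filter(mp, k, sides = 2)
  matrix(out[(half + 1):(half + n), ], n, ncol(m))
}

smooth_stack <- function(stack, sigma) {
  k <- gaussian_kernel(sigma)
  d <- dim(stack)
  # dim 1 (y)
  stack <- array(smooth_along_dim1(matrix(stack, d[1], d[2] * d[3]), k), d)
  # dim 2 (x)
  stack <- aperm(array(smooth_along_dim1(
    matrix(aperm(stack, c(2, 1, 3)), d[2], d[1] * d[3]), k),
    c(d[2], d[1], d[3])), c(2, 1, 3))
  # dim 3 (z)
  if (d[3] > 1) {
    stack <- aperm(array(smooth_along_dim1(
      matrix(aperm(stack, c(3, 1, 2)), d[3], d[1] * d[2]), k),
      c(d[3], d[1], d[2])), c(2, 3, 1))
  }
  stack
}

#' De-stripe and smooth an image stack
#'
#' Suppresses the horizontal scan-stripe artifact and denoises. The stripe
#' component of each slice is estimated as the per-row median (robust to
#' sparse bright droplets), high-pass filtered along the row axis by
#' subtracting a running mean of window `highpass_window` (so genuine
#' smooth background variation along y is kept), and subtracted from every
#' row. The result is then smoothed by a separable 3D Gaussian.
#'
#' @param stack Numeric array (y, x, z); a matrix is treated as one slice.
#' @param smooth_sigma Gaussian smoothing SD in voxels (> 0; use a small
#'   value such as 0.5 to keep droplet edges sharp). `NULL` skips the
#'   smoothing pass (de-striping only); a non-positive number is an error.
#' @param highpass_window Running-mean window (odd, voxels) separating the
#'   stripe band from genuine background variation along y.
#' @return Array of the same shape.
#' @export
destripe_and_smooth <- function(stack, smooth_sigma = 0.8,
                                highpass_window = 15) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  stopifnot(length(dim(stack)) == 3)
  if (!is.null(smooth_sigma) && (!is.finite(smooth_sigma) || smooth_sigma <= 0))
    stop("smooth_sigma must be > 0 (or NULL to skip smoothing)")
  w <- as.integer(highpass_window)
  if (w %% 2L == 0L) w <- w + 1L
  d <- dim(stack)
  for (z in seq_len(d[3])) {
    slice <- stack[, , z]
    rowmed <- apply(slice, 1, stats::median)
    half <- (w - 1L) / 2L
    padded <- c(rep(rowmed[1], half), rowmed, rep(rowmed[length(rowmed)], half))
    low <- stats::filter(padded, rep(1 / w, w), sides = 2)
    low <- low[(half + 1):(half + length(rowmed))]
    stripe <- rowmed - low
    stack[, , z] <- slice - stripe  # recycled down columns: per-row offset
  }
  if (is.null(smooth_sigma)) stack else smooth_stack(stack, smooth_sigma)
}

#' Otsu threshold of an intensity array
#'
#' Histogram-based Otsu threshold over all voxels (via [EBImage::otsu()],
#' applied to the flattened intensities scaled to their own range).
#'
#' @param x Numeric array.
#' @param levels Histogram levels.
#' @return Scalar threshold on the original intensity scale.
#' @export
otsu_threshold <- function(x, levels = 256) {
  v <- as.vector(x)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  EBImage::otsu(matrix(v, ncol = 1), range = rng, levels = levels)
}

#' Segment 3D lipid droplets
#'
#' Thresholds the (preprocessed) stack and groups above-threshold voxels by
#' 26-connectivity in 3D (connected components of the voxel adjacency
#' graph). Components smaller than `min_voxels` are discarded as noise.
#'
#' @param stack Numeric array (y, x, z).
#' @param threshold `"otsu"` (default) or a numeric intensity cutoff.
#' @param min_voxels Minimum droplet size in voxels (default 27).
#' @param voxel_size Length-3 numeric, micrometres per voxel along
#'   (y, x, z); used for volumes in um^3.
#' @param cell_id Optional identifier attached to each droplet.
#' @return List of `droplet` objects (possibly empty), each with `voxels`
#'   (n x 3 coordinates), `centroid`, `volume_voxels`, `volume_um3`,
#'   `cell_id`.
#' @export
segment_droplets <- function(stack, threshold = "otsu", min_voxels = 27,
                             voxel_size = c(1, 1, 1), cell_id = NA) {
  if (is.matrix(stack)) stack <- array(stack, dim = c(dim(stack), 1))
  stopifnot(length(dim(stack)) == 3)
  thr <- if (identical(threshold, "otsu")) otsu_threshold(stack)
         else as.numeric(threshold)
  fg <- which(stack > thr)
  if (!length(fg)) return(list())
  d <- dim(stack)
  coords <- arrayInd(fg, d)
  id_of <- array(0L, dim = d)
  id_of[fg] <- seq_along(fg)
  # half the 26-neighbourhood (undirected graph)
  offs <- as.matrix(expand.grid(dy = -1:1, dx = -1:1, dz = -1:1))
  offs <- offs[offs[, 3] > 0 | (offs[, 3] == 0 & (offs[, 2] > 0 |
            (offs[, 2] == 0 & offs[, 1] > 0))), , drop = FALSE]
  edges <- NULL
  for (r in seq_len(nrow(offs))) {
    nb <- coords + rep(offs[r, ], each = nrow(coords))
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    if (!any(ok)) next
    tgt <- id_of[nb[ok, , drop = FALSE]]
    src <- which(ok)[tgt > 0]
    if (length(src))
      edges <- rbind(edges, cbind(src, tgt[tgt > 0]))
  }
  g <- igraph::graph_from_edgelist(
    if (is.null(edges)) matrix(integer(), ncol = 2) else edges,
    directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(fg) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  droplets <- list()
  for (ci in seq_len(max(comp))) {
    vox <- coords[comp == ci, , drop = FALSE]
    if (nrow(vox) < min_voxels) next
    droplets[[length(droplets) + 1L]] <- structure(
      list(voxels = vox, centroid = colMeans(vox),
           volume_voxels = nrow(vox),
           volume_um3 = nrow(vox) * prod(voxel_size),
           cell_id = cell_id),
      class = "droplet")
  }
  droplets
}

#' @export
print.droplet <- function(x, ...) {
  cat(sprintf("<droplet> %d voxels at (%.1f, %.1f, %.1f)\n",
              x$volume_voxels, x$centroid[1], x$centroid[2], x$centroid[3]))
  invisible(x)
}

#' Sphericity score of a segmented droplet
#'
#' Radial-dispersion sphericity: with r_i the Euclidean distances from the
#' droplet's centre of mass to each surface voxel (voxels with at least one
#' 6-neighbour outside the droplet), the score is
#' `max(0, 1 - sd(r)/mean(r))` — 1 for an ideal sphere, smaller as the
#' surface departs from a sphere. A single-voxel droplet scores 1 by
#' convention (flagged via the `"degenerate"` attribute).
#'
#' @param droplet A `droplet` from [segment_droplets()].
#' @return Scalar in \[0, 1\].
#' @export
sphericity <- function(droplet) {
  stopifnot(inherits(droplet, "droplet"))
  vox <- droplet$voxels
  if (nrow(vox) == 1L) return(structure(1, degenerate = TRUE))
  lo <- apply(vox, 2, min) - 2L
  box <- array(FALSE, dim = apply(vox, 2, max) - lo + 2L)
  local <- sweep(vox, 2, lo)
  box[local] <- TRUE
  d <- dim(box)
  is_surface <- logical(nrow(local))
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    nb <- local
    nb[, ax] <- nb[, ax] + s
    is_surface <- is_surface | !box[nb]
  }
  surf <- vox[is_surface, , drop = FALSE]
  r <- sqrt(colSums((t(surf) - droplet$centroid)^2))
  max(0, 1 - stats::sd(r) / mean(r))
}

#' Filter droplets by sphericity and summarize per cell
#'
#' Discards droplets scoring below the sphericity threshold, then reports
#' per-cell droplet count and volume statistics.
#'
#' @param droplets List of `droplet` objects (from one or more cells; the
#'   `cell_id` field distinguishes cells).
#' @param sphericity_threshold Minimum score retained, in \[0, 1\]
#'   (default 0.6).
#' @return List with `per_cell` (data.frame: cell_id, count, mean_volume_voxels,
#'   mean_volume_um3 — `NA` when no droplet is retained), `volumes` (list of
#'   retained per-cell voxel volumes) and `retained` (the kept droplets).
#' @export
filter_and_summarize <- function(droplets, sphericity_threshold = 0.6) {
  stopifnot(sphericity_threshold >= 0, sphericity_threshold <= 1)
  scores <- vapply(droplets, function(d) as.numeric(sphericity(d)), 0)
  keep <- droplets[scores >= sphericity_threshold]
  cells <- unique(vapply(droplets, function(d) as.character(d$cell_id), ""))
  if (!length(cells)) cells <- NA_character_
  per_cell <- do.call(rbind, lapply(cells, function(cid) {
    k <- keep[vapply(keep, function(d) identical(as.character(d$cell_id), cid), TRUE)]
    vols <- vapply(k, `[[`, 0, "volume_voxels")
    data.frame(cell_id = cid, count = length(k),
               mean_volume_voxels = if (length(k)) mean(vols) else NA_real_,
               mean_volume_um3 = if (length(k))
                 mean(vapply(k, `[[`, 0, "volume_um3")) else NA_real_)
  }))
  vols <- lapply(cells, function(cid)
    vapply(keep[vapply(keep, function(d)
      identical(as.character(d$cell_id), cid), TRUE)], `[[`, 0, "volume_voxels"))
  names(vols) <- cells
  list(per_cell = per_cell, volumes = vols, retained = keep)
}
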