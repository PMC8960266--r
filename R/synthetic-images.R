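#' Phantom ground truth for droplet image stacks
#'
#' Describes the droplets to paint into a synthetic SRS stack: centres,
#' semi-axes (spheres when all three agree), per-droplet peak intensity,
#' background level. Coordinates are 1-based voxel indices ordered
#' (y, x, z) — rows, columns, slices.
#'
#' @param centers n x 3 matrix of droplet centres (y, x, z).
#' @param semi_axes n x 3 matrix of semi-axes in voxels (or a length-n
#'   vector of radii for spheres).
#' @param intensity Per-droplet peak intensity (scalar or length n).
#' @param background Background intensity level.
#' @return Object of class `phantom_truth`; `volume_analytic` holds
#'   (4/3) pi a b c per droplet, `overlapping` flags droplet pairs whose
#'   bounding spheres intersect.
#' @export
phantom_truth <- function(centers, semi_axes, intensity = 1,
                          background = 0.1) {
  centers <- matrix(as.numeric(centers), ncol = 3)
  if (is.vector(semi_axes) && is.null(dim(semi_axes)))
    semi_axes <- matrix(rep(as.numeric(semi_axes), 3), ncol = 3)
  semi_axes <- matrix(as.numeric(semi_axes), ncol = 3)
  stopifnot(nrow(centers) == nrow(semi_axes), all(semi_axes > 0))
  n <- nrow(centers)
  intensity <- rep_len(intensity, n)
  vol <- 4 / 3 * pi * apply(semi_axes, 1, prod)
  overlapping <- rep(FALSE, n)
  if (n > 1) {
    rmax <- apply(semi_axes, 1, max)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (sqrt(sum((centers[i, ] - centers[j, ])^2)) < rmax[i] + rmax[j])
        overlapping[c(i, j)] <- TRUE
    }
  }
  structure(list(centers = centers, semi_axes = semi_axes,
                 intensity = intensity, background = background,
                 volume_analytic = vol, overlapping = overlapping),
            class = "phantom_truth")
}

#' Random non-overlapping spherical droplet truth
#'
#' Places `n` spheres with radii drawn uniformly from `radius_range` inside
#' the stack, fully within bounds and pairwise non-overlapping (rejection
#' sampling).
#'
#' @param n Number of droplets.
#' @param radius_range Length-2 numeric, voxel radius range.
#' @param shape Stack dimensions (y, x, z).
#' @param seed Integer seed.
#' @param margin Extra clearance from the boundary (voxels).
#' @inheritParams phantom_truth
#' @return A [phantom_truth()].
#' @export
random_droplet_truth <- function(n, radius_range = c(6, 10),
                                 shape = c(64, 64, 64), seed = 1L,
                                 margin = 1, intensity = 1,
                                 background = 0.1) {
  set.seed(seed)
  centers <- matrix(NA_real_, n, 3)
  radii <- numeric(n)
  placed <- 0L
  tries <- 0L
  while (placed < n) {
    tries <- tries + 1L
    if (tries > 20000L) stop("could not place ", n, " non-overlapping droplets")
    r <- stats::runif(1, radius_range[1], radius_range[2])
    ctr <- vapply(1:3, function(d)
      stats::runif(1, r + margin + 1, shape[d] - r - margin), 0)
    # keep a 4-voxel clearance between surfaces so smoothing at the usual
    # scales never bridges neighbouring droplets into one component
    ok <- placed == 0L ||
      all(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) - ctr)^2)) >
            radii[seq_len(placed)] + r + 4)
    if (ok) {
      placed <- placed + 1L
      centers[placed, ] <- ctr
      radii[placed] <- r
    }
  }
  phantom_truth(centers, radii, intensity, background)
}

#' Generate a 3D droplet image stack from a phantom truth
#'
#' Paints each droplet as a filled ellipsoid of its peak intensity over the
#' background, then adds the horizontal scan-stripe artifact (an additive
#' per-row sinusoid plus offset, constant along the fast-scan x axis, with
#' a per-slice random phase) and iid Gaussian noise. The truth is returned
#' unchanged except that voxelized per-droplet volumes are filled in.
#'
#' @param truth A [phantom_truth()]; droplets must lie fully inside `shape`.
#' @param shape Stack dimensions (y, x, z).
#' @param noise_sd Additive Gaussian noise SD (>= 0).
#' @param stripe_amp Stripe amplitude (0 disables).
#' @param stripe_period Stripe period along y (voxels).
#' @param seed Integer seed.
#' @return List with `stack` (numeric array y, x, z), `truth` (the input
#'   with `volume_voxels` added), and `mask` (integer array labelling each
#'   droplet's noise-free voxels).
#' @export
generate_droplet_stack <- function(truth, shape = c(64, 64, 64),
                                   noise_sd = 0, stripe_amp = 0,
                                   stripe_period = 8, seed = 1L) {
  stopifnot(inherits(truth, "phantom_truth"))
  lo <- truth$centers - truth$semi_axes
  hi <- truth$centers + truth$semi_axes
  if (any(lo < 1) || any(hi > rep(shape, each = nrow(truth$centers))))
    stop("droplets must lie fully inside the stack")
  set.seed(seed)
  stack <- array(truth$background, dim = shape)
  mask <- array(0L, dim = shape)
  vol <- integer(nrow(truth$centers))
  for (i in seq_len(nrow(truth$centers))) {
    c0 <- truth$centers[i, ]; ax <- truth$semi_axes[i, ]
    yr <- max(1, floor(c0[1] - ax[1])):min(shape[1], ceiling(c0[1] + ax[1]))
    xr <- max(1, floor(c0[2] - ax[2])):min(shape[2], ceiling(c0[2] + ax[2]))
    zr <- max(1, floor(c0[3] - ax[3])):min(shape[3], ceiling(c0[3] + ax[3]))
    g <- expand.grid(y = yr, x = xr, z = zr)
    inside <- ((g$y - c0[1]) / ax[1])^2 + ((g$x - c0[2]) / ax[2])^2 +
      ((g$z - c0[3]) / ax[3])^2 <= 1
    idx <- cbind(g$y, g$x, g$z)[inside, , drop = FALSE]
    stack[idx] <- truth$background + truth$intensity[i]
    mask[idx] <- i
    vol[i] <- nrow(idx)
  }
  if (stripe_amp > 0) {
    phase <- stats::runif(shape[3], 0, 2 * pi)
    for (z in seq_len(shape[3])) {
      srow <- stripe_amp * (0.5 + 0.5 * sin(2 * pi * seq_len(shape[1]) /
                                              stripe_period + phase[z]))
      stack[, , z] <- stack[, , z] + srow  # recycles down columns (along y)
    }
  }
  if (noise_sd > 0)
    stack <- stack + array(stats::rnorm(prod(shape), 0, noise_sd), dim = shape)
  truth$volume_voxels <- vol
  list(stack = stack, truth = truth, mask = mask)
}

#' Generate a flavin/NADH autofluorescence image pair
#'
#' Paints disk-shaped cells at non-overlapping random positions, assigns
#' each channel its per-cell mean level, and adds a smooth planar background
#' gradient (what rolling-ball subtraction is meant to remove) plus iid
#' Gaussian noise.
#'
#' @param shape Image dimensions (y, x).
#' @param n_cells Number of cells.
#' @param cell_radius Disk radius (pixels).
#' @param flavin_level,nadh_level Per-cell intensity (scalar or length
#'   `n_cells`), >= 0.
#' @param gradient_amp Amplitude of the planar background ramp (0 disables).
#' @param noise_sd Additive noise SD.
#' @param seed Integer seed.
#' @return List with `flavin`, `nadh` (matrices), `masks` (integer matrix,
#'   0 = background, i = cell i) and `background` (the clean gradient).
#' @export
generate_fluorescence_pair <- function(shape = c(192, 192), n_cells = 4,
                                       cell_radius = 18,
                                       flavin_level = 1, nadh_level = 1,
                                       gradient_amp = 0, noise_sd = 0,
                                       seed = 1L) {
  stopifnot(all(flavin_level >= 0), all(nadh_level >= 0))
  set.seed(seed)
  flavin_level <- rep_len(flavin_level, n_cells)
  nadh_level <- rep_len(nadh_level, n_cells)
  masks <- matrix(0L, shape[1], shape[2])
  centers <- matrix(NA_real_, max(n_cells, 1), 2)
  placed <- 0L; tries <- 0L
  while (placed < n_cells) {
    tries <- tries + 1L
    if (tries > 10000L) stop("could not place non-overlapping cells")
    ctr <- c(stats::runif(1, cell_radius + 2, shape[1] - cell_radius - 1),
             stats::runif(1, cell_radius + 2, shape[2] - cell_radius - 1))
    if (placed > 0L &&
        any(sqrt(colSums((t(centers[seq_len(placed), , drop = FALSE]) - ctr)^2)) <
              2 * cell_radius + 4)) next
    placed <- placed + 1L
    centers[placed, ] <- ctr
  }
  yy <- row(masks); xx <- col(masks)
  for (i in seq_len(n_cells)) {
    sel <- (yy - centers[i, 1])^2 + (xx - centers[i, 2])^2 <= cell_radius^2
    masks[sel] <- i
  }
  background <- gradient_amp * ((yy - 1) / (shape[1] - 1) +
                                  (xx - 1) / (shape[2] - 1)) / 2
  paint <- function(levels) {
    img <- matrix(0, shape[1], shape[2])
    for (i in seq_len(n_cells)) img[masks == i] <- levels[i]
    img <- img + background
    if (noise_sd > 0)
      img <- img + matrix(stats::rnorm(prod(shape), 0, noise_sd),
                          shape[1], shape[2])
    img
  }
  list(flavin = paint(flavin_level), nadh = paint(nadh_level),
       masks = masks, background = background)
}

#' Droplet-morphology scenario phantoms
#'
#' Ground-truth stacks for the morphology contrast the study reports:
#' excess methionine yields fewer but larger lipid droplets. Each cell is
#' one stack; per-cell droplet counts jitter around the group mean and radii
#' are drawn from group-specific ranges.
#'
#' @param group `"control"` (more, smaller droplets: ~12 of radius 5.5-7.5
#'   voxels) or `"excess_met"` (fewer, larger: ~6 of radius 7.5-9.5 voxels).
#' @param n_cells Cells (stacks) to generate.
#' @param shape Stack dimensions.
#' @param noise_sd Additive noise SD (default 0.1, SNR 10 against unit
#'   droplet intensity).
#' @param seed Integer seed.
#' @return List of per-cell results as returned by
#'   [generate_droplet_stack()], with `cell_id` fields `"<group>_<i>"`.
#' @export
morphology_scenario <- function(group = c("control", "excess_met"),
                                n_cells = 4, shape = c(64, 64, 64),
                                noise_sd = 0.1, seed = 1L) {
  group <- match.arg(group)
  set.seed(seed)
  base <- if (group == "control") 12L else 6L
  radius_range <- if (group == "control") c(5.5, 7.5) else c(7.5, 9.5)
  lapply(seq_len(n_cells), function(i) {
    n <- max(2L, base + sample(-2:2, 1))
    tr <- random_droplet_truth(n, radius_range, shape,
                               seed = sample.int(1e6, 1))
    out <- generate_droplet_stack(tr, shape, noise_sd = noise_sd,
                                  stripe_amp = 0.2,
                                  seed = sample.int(1e6, 1))
    out$cell_id <- sprintf("%s_%d", group, i)
    out
  })
}
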