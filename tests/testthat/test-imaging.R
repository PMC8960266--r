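sphere_stack <- function(radius = 8, noise_sd = 0, stripe_amp = 0, seed = 1) {
  tr <- phantom_truth(matrix(c(32, 32, 32), 1), radius)
  generate_droplet_stack(tr, noise_sd = noise_sd, stripe_amp = stripe_amp,
                         seed = seed)
}

test_that("de-striping removes the stripe band and little else", {
  # stripe-free, noise-free phantom: de-striping alone is a near no-op
  g0 <- sphere_stack(noise_sd = 0, stripe_amp = 0)
  out0 <- destripe_and_smooth(g0$stack, smooth_sigma = NULL)
  expect_lt(sqrt(mean((out0 - g0$stack)^2)) / sqrt(mean(g0$stack^2)), 0.02)

  # on an un-smoothed copy the de-striping step itself is a near no-op:
  # compare the stripe component before and after
  gs <- sphere_stack(noise_sd = 0.05, stripe_amp = 0.5, seed = 2)
  stripe_power <- function(st) mean(apply(st, 3, function(sl) {
    rm <- apply(sl, 1, mean)
    mean((rm - mean(rm))^2)
  }))
  before <- stripe_power(gs$stack)
  after <- stripe_power(destripe_and_smooth(gs$stack, smooth_sigma = 0.5))
  expect_lt(after / before, 0.1)  # >= 90% stripe power suppressed

  const <- array(2, dim = c(16, 16, 4))
  out_c <- destripe_and_smooth(const, smooth_sigma = 0.8)
  expect_equal(out_c, const, tolerance = 1e-12)

  expect_error(destripe_and_smooth(const, smooth_sigma = 0), "smooth_sigma")
})

test_that("segmentation recovers phantom droplets and volumes", {
  two <- phantom_truth(rbind(c(18, 18, 18), c(48, 48, 48)), c(7, 7))
  g2 <- generate_droplet_stack(two, noise_sd = 0)
  expect_length(segment_droplets(g2$stack, threshold = 0.5), 2L)
  expect_length(segment_droplets(g2$stack,
                                 threshold = max(g2$stack) + 1), 0L)

  g <- sphere_stack(radius = 8, noise_sd = 0.1, seed = 5)  # SNR 10
  dr <- segment_droplets(destripe_and_smooth(g$stack, smooth_sigma = 0.8))
  expect_length(dr, 1L)
  expect_lt(abs(dr[[1]]$volume_voxels - g$truth$volume_voxels) /
              g$truth$volume_voxels, 0.15)
  expect_lt(max(abs(dr[[1]]$centroid - c(32, 32, 32))), 1)
  # volumes in um^3 follow the voxel size
  dr2 <- segment_droplets(destripe_and_smooth(g$stack, smooth_sigma = 0.8),
                          voxel_size = c(0.5, 0.5, 1))
  expect_equal(dr2[[1]]$volume_um3, dr2[[1]]$volume_voxels * 0.25)
})

test_that("sphericity ranks spheres above ellipsoids and is scale-stable", {
  seg1 <- function(truth, shape = c(64, 64, 64)) {
    g <- generate_droplet_stack(truth, shape, noise_sd = 0)
    segment_droplets(g$stack, threshold = 0.5)[[1]]
  }
  s8 <- sphericity(seg1(phantom_truth(matrix(c(32, 32, 32), 1), 8)))
  expect_gte(s8, 0.9)

  # fixed volume, growing axis ratio: score strictly decreases
  vol_r <- 8
  scores <- vapply(c(1, 1.5, 2, 3), function(ar) {
    a <- vol_r * ar^(2 / 3); bc <- vol_r / ar^(1 / 3)
    sphericity(seg1(phantom_truth(matrix(c(40, 32, 32), 1),
                                  matrix(c(a, bc, bc), 1),),
                    shape = c(80, 64, 64)))
  }, 0)
  expect_true(all(diff(scores) < 0))
  expect_gt(s8, scores[4])

  # doubling the radius changes the score by less than 0.05
  s16 <- sphericity(seg1(phantom_truth(matrix(c(40, 40, 40), 1), 16),
                         shape = c(80, 80, 80)))
  expect_lt(abs(s16 - s8), 0.05)

  single <- structure(list(voxels = matrix(c(3, 3, 3), 1),
                           centroid = c(3, 3, 3), volume_voxels = 1,
                           volume_um3 = 1, cell_id = NA),
                      class = "droplet")
  sc <- sphericity(single)
  expect_equal(as.numeric(sc), 1)
  expect_true(attr(sc, "degenerate"))
})

test_that("sphericity filtering and per-cell summaries follow the truth", {
  tr <- phantom_truth(rbind(c(16, 16, 16), c(16, 48, 16), c(48, 16, 16)),
                      c(7, 7, 7))
  g <- generate_droplet_stack(tr, noise_sd = 0)
  ell <- generate_droplet_stack(
    phantom_truth(matrix(c(48, 48, 44), 1), matrix(c(4, 16, 4), 1)),
    noise_sd = 0)
  stack <- pmax(g$stack, ell$stack)
  dr <- segment_droplets(stack, threshold = 0.5, cell_id = "cell1")
  expect_length(dr, 4L)
  scores <- vapply(dr, function(d) as.numeric(sphericity(d)), 0)
  thr <- (max(scores[rank(scores) <= 1]) + min(scores[rank(scores) > 1])) / 2
  filt <- filter_and_summarize(dr, sphericity_threshold = thr)
  expect_equal(filt$per_cell$count, 3L)
  expect_equal(nrow(filt$per_cell), 1L)

  all_kept <- filter_and_summarize(dr, sphericity_threshold = 0)
  expect_equal(all_kept$per_cell$count, 4L)

  none <- filter_and_summarize(dr, sphericity_threshold = 1)
  expect_equal(none$per_cell$count, 0L)
  expect_true(is.na(none$per_cell$mean_volume_voxels))

  # two identical cells: zero spread in count
  dr_a <- segment_droplets(g$stack, threshold = 0.5, cell_id = "a")
  dr_b <- segment_droplets(g$stack, threshold = 0.5, cell_id = "b")
  both <- filter_and_summarize(c(dr_a, dr_b), 0.5)
  expect_equal(sd(both$per_cell$count), 0)
})

test_that("morphological background subtraction flattens smooth backgrounds", {
  flat <- matrix(0.7, 96, 96)
  rb <- subtract_image_background(flat, "rolling_ball", 30)
  expect_lt(max(abs(rb$subtracted)), 1e-9)
  sp <- subtract_image_background(flat, "sliding_paraboloid", 30)
  expect_lt(max(abs(sp$subtracted)), 1e-9)

  fp <- generate_fluorescence_pair(shape = c(192, 192), flavin_level = 1,
                                   nadh_level = 1, gradient_amp = 4,
                                   noise_sd = 0.01, seed = 7)
  outside <- fp$masks == 0
  for (method in c("rolling_ball", "sliding_paraboloid")) {
    res <- subtract_image_background(fp$flavin, method, 50)
    expect_gte(1 - sqrt(mean(res$subtracted[outside]^2)) /
                 sqrt(mean(fp$flavin[outside]^2)), 0.8)
    expect_true(all(res$background <= fp$flavin + 1e-9))
  }

  # growing the radius approaches plain minimum subtraction
  set.seed(8)
  img <- matrix(runif(32 * 32, 1, 2), 32, 32)
  err <- vapply(c(8, 16, 32), function(r)
    mean(abs(subtract_image_background(img, "rolling_ball", r)$subtracted -
               (img - min(img)))), 0)
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.4)
  expect_error(subtract_image_background(img, "rolling_ball", 100),
               "larger than the image")
  expect_error(subtract_image_background(img, "rolling_ball", -1), "radius")
})

test_that("redox maps are correct, bounded and mask-aware", {
  f <- matrix(2, 8, 8); n <- matrix(2, 8, 8)
  expect_true(all(redox_map(f, n)$map == 0.5))
  expect_true(all(redox_map(f, matrix(0, 8, 8))$map == 1))
  masks <- matrix(0L, 8, 8); masks[2:4, 2:4] <- 1L
  r <- redox_map(matrix(1, 8, 8), matrix(3, 8, 8), masks)
  expect_equal(r$per_cell$mean_ratio, 0.25)
  zero <- matrix(0, 8, 8)
  expect_true(all(is.na(redox_map(zero, zero)$map)))
  set.seed(1)
  rr <- redox_map(matrix(runif(64), 8, 8), matrix(runif(64), 8, 8))$map
  expect_true(all(rr >= 0 & rr <= 1, na.rm = TRUE))
  expect_error(redox_map(f, matrix(1, 4, 4)), "shape")
})

test_that("region quantification: lines, histograms, projections", {
  const <- matrix(3, 32, 32)
  lp <- line_profile(const, c(2, 2), c(30, 30))
  expect_equal(lp$intensity, rep(3, 200))
  expect_error(line_profile(const, c(5, 5), c(5, 5)), "zero-length")

  # bilinear interpolation is exact on a linear ramp
  ramp <- outer(1:32, 1:32, function(y, x) 2 * y + 3 * x)
  lp2 <- line_profile(ramp, c(4, 4), c(28, 20), n_points = 50)
  ys <- seq(4, 28, length.out = 50); xs <- seq(4, 20, length.out = 50)
  expect_equal(lp2$intensity, 2 * ys + 3 * xs, tolerance = 1e-9)

  stack <- array(0, dim = c(16, 16, 6))
  stack[5, 9, 3] <- 7
  mip <- max_intensity_projection(stack)
  expect_equal(mip[5, 9], 7)
  expect_equal(sum(mip), 7)
  expect_identical(region_quantify(stack, "whole"), mip)

  masks <- matrix(0L, 40, 40)
  masks[2:10, 2:10] <- 1L; masks[20:28, 20:28] <- 2L
  img <- matrix(0.5, 40, 40)
  img[masks == 1] <- rep(c(0.2, 0.8), length.out = sum(masks == 1))
  img[masks == 2] <- rep(c(0.2, 0.8), length.out = sum(masks == 2))
  h <- mask_histograms(img, masks, breaks = 8)
  expect_true(all(h$sem == 0))  # identical per-cell histograms
  expect_equal(rowSums(h$per_cell), c(`1` = 1, `2` = 1))
})

test_that("stacks roundtrip through multi-page TIFF", {
  set.seed(4)
  st <- array(runif(16 * 16 * 5), dim = c(16, 16, 5))
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(st, path)
  back <- read_image_stack(path)
  expect_equal(dim(back), dim(st))
  expect_equal(back, st, tolerance = 1e-6)
})
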