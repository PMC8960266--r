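test_that("class distribution fitting floors degenerate SDs", {
  grid <- 1:20
  mk <- function(int, g, i) raman_spectrum(grid, int, list(grp = g, id = i))
  s <- spectrum_set(list(mk(rep(1, 20), "a", 1), mk(rep(1, 20), "a", 2),
                         mk(rep(2, 20), "b", 1), mk(rep(0, 20), "b", 2)))
  m <- fit_class_distributions(s, "grp")
  expect_true(all(m$sigma["a", ] == m$sigma_floor))
  # two spectra {0, 2} at every wavenumber: mu = 1, sd = sqrt(2)
  expect_true(all(m$mu["b", ] == 1))
  expect_true(all(abs(m$sigma["b", ] - sqrt(2)) < 1e-12))

  lone <- spectrum_set(list(mk(rep(1, 20), "a", 1), mk(rep(1, 20), "a", 2),
                            mk(rep(2, 20), "b", 1)))
  expect_error(fit_class_distributions(lone, "grp"), "b")
})

test_that("discretized Gaussians are proper, symmetric and centred", {
  p <- discretize_gaussian(0, 1, c(-6, 6), 1e4)
  expect_equal(sum(p$p), 1, tolerance = 1e-12)
  expect_equal(p$p, rev(p$p), tolerance = 1e-12)
  expect_lt(abs(sum(p$p * p$centers) - 0), diff(p$support) / p$L / 2)
  p2 <- discretize_gaussian(2.5, 0.7, c(-3, 8), 1e5)
  expect_lt(abs(sum(p2$p * p2$centers) - 2.5), diff(p2$support) / p2$L / 2)
  expect_error(discretize_gaussian(0, 1, c(-6, 6), 500), "1000")
})

test_that("cross entropy, KL and symmetric KL match Gaussian closed forms", {
  sup <- pair_support(0, 1, 1, 1)
  pA <- discretize_gaussian(0, 1, sup, 1e5)
  pB <- discretize_gaussian(1, 1, sup, 1e5)
  # H(A,A) is the Shannon entropy; H(A,B) = H(A,A) + KL(A||B)
  expect_equal(cross_entropy(pA, pA), -sum(pA$p * log(pA$p)))
  expect_lt(abs(cross_entropy(pA, pB) - cross_entropy(pA, pA) -
                  kl_divergence(pA, pB)), 1e-9)
  expect_lt(abs(cross_entropy(pA, pB) - cross_entropy(pA, pA) - 0.5), 0.005)

  expect_equal(kl_divergence(pA, pA), 0)
  sup2 <- pair_support(0, 1, 0, 2)
  qA <- discretize_gaussian(0, 1, sup2, 1e5)
  qB <- discretize_gaussian(0, 2, sup2, 1e5)
  expect_lt(abs(kl_divergence(qA, qB) / gaussian_kl_closed(0, 1, 0, 2) - 1),
            0.01)  # 0.3181 nats
  expect_lt(abs(kl_divergence(qB, qA) / gaussian_kl_closed(0, 2, 0, 1) - 1),
            0.01)  # 0.8069 nats
  expect_equal(symmetric_kl(qA, qB), symmetric_kl(qB, qA))
  expect_lt(abs(symmetric_kl(qA, qB) - (0.3181 + 0.8069) / 2), 0.006)

  other <- discretize_gaussian(0, 1, sup2 + 1, 1e5)
  expect_error(kl_divergence(qA, other), "support")
})

test_that("multiclass divergence reduces to the pairwise form at k = 2", {
  sup <- pair_support(0, 1, 2, 1.5)
  v <- list(discretize_gaussian(0, 1, sup, 1e4),
            discretize_gaussian(2, 1.5, sup, 1e4))
  expect_identical(multiclass_divergence(v), symmetric_kl(v[[1]], v[[2]]))
  expect_equal(multiclass_divergence(list(v[[1]], v[[1]], v[[1]])), 0)
  expect_error(multiclass_divergence(v[1]), "at least 2")

  # k = 3: hand-summed closed-form pairwise KLs
  mus <- c(0, 1, 2); sds <- c(1, 1.3, 0.8)
  sup3 <- c(min(mus) - 6 * max(sds), max(mus) + 6 * max(sds))
  v3 <- lapply(1:3, function(i) discretize_gaussian(mus[i], sds[i], sup3, 1e5))
  hand <- 0
  for (i in 1:3) for (j in 1:3) if (i != j)
    hand <- hand + gaussian_kl_closed(mus[i], sds[i], mus[j], sds[j])
  hand <- hand / 6
  expect_lt(abs(multiclass_divergence(v3) / hand - 1), 0.01)
})

test_that("entropy profiles localize the discriminating band", {
  co <- shifted_cohort("unsat_3010", 1 + 2 * 0.02 / 0.25, seed = 21,
                       cells_per_group = 5)
  prof <- entropy_profile(co$set, "methionine_x", L = 5e3)
  amax <- prof$wavenumber[which.max(prof$score)]
  expect_lt(abs(amax - 3010), 25)  # within one FWHM of the shifted band
  expect_true(all(prof$score >= 0))
  expect_equal(prof$k, 2L)
  expect_true(any(abs(prof$top$wavenumber[1:5] - 3010) <= 25))
})

test_that("null profiles are near zero and profiles are scale/label invariant", {
  co <- generate_spectrum_cohort(cohort_design(
    cell_lines = "X", methionine_x = c(1, 20), insulin_x = 1,
    cells_per_group = 10, spectra_per_cell = 5, noise_sd = 0.02, seed = 31,
    grid = seq(2600, 3200, by = 2)))
  prof <- entropy_profile(co$set, "methionine_x", L = 5e3)
  # sampling noise in the fitted class Gaussians floors the null divergence
  # at O(1/n) per wavenumber, with the grid-wide max a few tenths of a nat;
  # a genuine 2-sd band shift scores ~2 nats, an order of magnitude above
  expect_lt(max(prof$score), 0.6)
  expect_lt(mean(prof$score), 0.1)

  # scaling all intensities leaves scores unchanged (data-driven support)
  sc <- co$set; sc$intensity <- sc$intensity * 7.3
  prof_sc <- entropy_profile(sc, "methionine_x", L = 5e3)
  expect_equal(prof_sc$score, prof$score, tolerance = 1e-8)

  # relabelling classes leaves the profile unchanged
  rl <- co$set
  rl$meta$methionine_x <- ifelse(rl$meta$methionine_x == "1", "z", "a")
  expect_equal(entropy_profile(rl, "methionine_x", L = 5e3)$score, prof$score,
               tolerance = 1e-12)
})

test_that("profile score is monotone in the between-class mean gap", {
  gaps <- c(1.0, 1.2, 1.5, 2.0)
  scores <- vapply(gaps, function(g) {
    co <- shifted_cohort("unsat_3010", g, seed = 41, cells_per_group = 5,
                         spectra_per_cell = 5)
    prof <- entropy_profile(co$set, "methionine_x", L = 2e3)
    prof$score[co$set$wavenumber == 3010]
  }, 0)
  expect_true(all(diff(scores) >= 0))
})

test_that("graded three-class shifts rank the band for the true factor only", {
  m <- list("X|met1|ins0.1" = c(ch2_2850 = 0.8),
            "X|met1|ins2"  = c(ch2_2850 = 1.2))
  co <- generate_spectrum_cohort(cohort_design(
    cell_lines = "X", methionine_x = 1, insulin_x = c(0.1, 1, 2),
    cells_per_group = 5, spectra_per_cell = 5, noise_sd = 0.02,
    multipliers = m, seed = 51, grid = seq(2600, 3200, by = 2)))
  prof <- entropy_profile(co$set, "insulin_x", L = 5e3)
  expect_equal(prof$k, 3L)
  expect_true(any(abs(prof$top$wavenumber[1:5] - 2850) <= 15))
  # permuted labels: 2850 should not dominate
  set.seed(1)
  perm <- co$set
  perm$meta$insulin_x <- sample(perm$meta$insulin_x)
  prof_p <- entropy_profile(perm, "insulin_x", L = 5e3)
  expect_lt(prof_p$score[perm$wavenumber == 2850] ,
            prof$score[co$set$wavenumber == 2850])
})
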