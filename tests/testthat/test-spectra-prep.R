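test_that("spectrum tables roundtrip through disk", {
  s <- generate_ld_spectrum(seed = 1, noise_sd = 0.01,
                            metadata = list(cell_line = "MCF10A"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_spectrum_table(s, path)
  s2 <- read_spectrum_table(path, metadata = list(cell_line = "MCF10A"))
  expect_equal(s2$wavenumber, s$wavenumber)
  expect_equal(s2$intensity, s$intensity)

  # descending file comes back sorted, same spectrum
  desc <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("wavenumber\tintensity",
               paste(rev(s$wavenumber), rev(s$intensity), sep = "\t")), desc)
  expect_warning(s3 <- read_spectrum_table(desc), "sorting")
  expect_equal(s3$intensity, s$intensity)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("100\t1.0", "oops\tnot_a_number", "102\t1.2"), bad)
  expect_error(read_spectrum_table(bad), "line 2")

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("100\t1.0", "100\t1.1"), dup)
  expect_error(read_spectrum_table(dup), "duplicate")

  expect_error(raman_spectrum(numeric(0), numeric(0)), "empty")
})

test_that("background subtraction is pointwise and metadata-preserving", {
  s <- generate_ld_spectrum(seed = 2, noise_sd = 0.01,
                            metadata = list(droplet_id = 3))
  expect_true(all(subtract_background(s, s)$intensity == 0))
  zero <- raman_spectrum(s$wavenumber, rep(0, length(s$wavenumber)))
  out <- subtract_background(s, zero)
  expect_equal(out$intensity, s$intensity)
  expect_equal(out$metadata$droplet_id, 3)

  other <- generate_ld_spectrum(grid = seq(600, 3200, by = 2), seed = 2)
  expect_error(subtract_background(s, other), "grids differ")

  # constructed decomposition: LD + smooth background recovers LD bands
  grid <- seq(600, 3200, by = 1)
  ld <- generate_ld_spectrum(noise_sd = 0, grid = grid)
  bgshape <- raman_spectrum(grid, 0.2 + 1e-4 * (grid - 600))
  noise_sd <- 0.01
  measured <- raman_spectrum(grid, ld$intensity + bgshape$intensity +
                               rnorm(length(grid), 0, noise_sd))
  rec <- subtract_background(measured, bgshape)
  for (ctr in ld_reference_bands()$center)
    expect_lt(abs(peak_intensity(rec, ctr) - peak_intensity(ld, ctr)),
              3 * noise_sd)
})

test_that("normalizations satisfy their contracts and are idempotent", {
  s <- generate_ld_spectrum(seed = 3, noise_sd = 0.02)
  v <- normalize_spectrum(s, "vector")
  expect_equal(sqrt(sum(v$intensity^2)), 1)
  v2 <- normalize_spectrum(v, "vector")
  expect_equal(v2$intensity, v$intensity, tolerance = 1e-12)

  sm <- normalize_spectrum(raman_spectrum(s$wavenumber, abs(s$intensity)),
                           "simplex")
  expect_equal(sum(sm$intensity), 1)

  neg <- raman_spectrum(1:5, c(-1, 0, 1, 2, 3))
  expect_warning(smn <- normalize_spectrum(neg, "simplex"), "shifting")
  expect_equal(sum(smn$intensity), 1)
  expect_equal(smn$metadata$simplex_shift, 1)

  p <- normalize_spectrum(s, "peak", at = 2940)
  expect_equal(max(p$intensity[abs(p$wavenumber - 2940) <= 5]), 1)

  zero <- raman_spectrum(1:4, rep(0, 4))
  expect_error(normalize_spectrum(zero, "vector"), "all-zero")
  expect_error(normalize_spectrum(zero, "simplex"), "all-zero")

  # numeric ops never alter labels; the chain is recorded
  s$metadata$cell_line <- "MDA-MB-231"
  chained <- suppressWarnings(
    normalize_spectrum(normalize_spectrum(s, "vector"), "simplex"))
  expect_equal(chained$metadata$cell_line, "MDA-MB-231")
  expect_equal(chained$metadata$preprocessing,
               c("normalize_vector", "normalize_simplex"))
})

test_that("group averages report per-point mean and sample SD", {
  grid <- 1:50
  base <- sin(grid / 5)
  mk <- function(int, g) raman_spectrum(grid, int, list(grp = g))
  idset <- spectrum_set(list(mk(base, "a"), mk(base, "a")))
  ga <- group_average(idset, "grp")
  expect_true(all(ga$sd == 0))

  # two spectra differing by constant c: SD = c/sqrt(2) everywhere
  cset <- spectrum_set(list(mk(base, "a"), mk(base + 3, "a")))
  expect_equal(group_average(cset, "grp")$sd, rep(3 / sqrt(2), 50))

  single <- spectrum_set(list(mk(base, "a"), mk(base, "b"), mk(base, "b")))
  gs <- group_average(single, "grp")
  expect_true(all(is.na(gs$sd[gs$group == "a"])))
  expect_true(all(gs$sd[gs$group == "b"] == 0))

  # cohort group mean within 3 SE of the design mean at a band centre
  co <- shifted_cohort("unsat_3010", 1.5, seed = 5, cells_per_group = 10)
  ga2 <- group_average(co$set, "methionine_x")
  at <- which(co$set$wavenumber == 3010)
  hi <- ga2[ga2$group == "20" & ga2$wavenumber == 3010, ]
  mu_true <- generate_ld_spectrum(local({
    b <- ld_reference_bands(); b["unsat_3010", "amplitude"] <-
      1.5 * b["unsat_3010", "amplitude"]; b
  }), noise_sd = 0)$intensity[at]
  expect_lt(abs(hi$mean - mu_true), 3 * hi$sd / sqrt(hi$n))
})
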