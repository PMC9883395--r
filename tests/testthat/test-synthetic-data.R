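test_that("default peak table matches the reported band assignments", {
  pk <- default_peak_table()
  grid <- wavenumber_grid()

  phe <- pk[pk$center == 1004, ]
  expect_equal(nrow(phe), 1L)
  expect_identical(phe$assignment, "phenylalanine")

  expect_true(all(pk$dose_coefficient[pk$center %in% c(790, 812)] < 0))
  up <- c(720, 1063, 1126, 1448, 1658, 851, 928, 620, 1004, 827)
  expect_true(all(pk$dose_coefficient[pk$center %in% up] > 0))

  expect_true(all(pk$base_amplitude >= 0))
  expect_true(all(pk$width > 0))
  expect_true(all(pk$center >= grid$start & pk$center <= grid$end))
})

test_that("dataset size is the product of the configured counts", {
  cfg <- generator_config(n_mice_per_arm = 5, sections_per_mouse = 3,
                          maps_per_section = 2, spectra_per_map = 10,
                          doses = 15, seed = 1)
  ds <- generate_dataset(cfg)
  expect_equal(nrow(ds$intensities), 5 * 3 * 2 * 10)
  expect_equal(ncol(ds$intensities), 582)
  key <- with(ds$meta, paste(mouse_id, section_id, map_id, spectrum_index))
  expect_false(anyDuplicated(key) > 0)
  expect_true(all(ds$meta$label == "irradiated"))
})

test_that("null effect with all randomness off makes doses identical", {
  cfg <- generator_config(peaks = default_peak_table(0),
                          n_mice_per_arm = 2, spectra_per_map = 3,
                          doses = c(0, 15), mouse_sd = 0, section_sd = 0,
                          map_sd = 0, noise_sd = 0, baseline_amplitude = 0,
                          seed = 5)
  ds <- generate_dataset(cfg)
  x0 <- ds$intensities[ds$meta$dose_gy == 0, , drop = FALSE]
  x15 <- ds$intensities[ds$meta$dose_gy == 15, , drop = FALSE]
  expect_equal(x0, x15, tolerance = 0)
  # and all rows within an arm are identical too
  expect_true(all(abs(sweep(x0, 2, x0[1, ])) < 1e-15))
})

test_that("generation is deterministic for a fixed seed", {
  cfg <- generator_config(n_mice_per_arm = 2, spectra_per_map = 2,
                          seed = 99)
  a <- generate_dataset(cfg)
  b <- generate_dataset(cfg)
  expect_identical(a$intensities, b$intensities)
  expect_identical(a$meta, b$meta)
})

test_that("generated spectra are non-negative and area-normalized", {
  cfg <- generator_config(n_mice_per_arm = 2, spectra_per_map = 3, seed = 2)
  ds <- generate_dataset(cfg)
  expect_true(all(ds$intensities >= 0))
  areas <- apply(ds$intensities, 1, function(y) trapz_area(ds$grid, y))
  expect_true(all(abs(areas - 1) < 1e-9))
})

test_that("invalid generator configuration names the offending field", {
  expect_error(generator_config(n_mice_per_arm = 0), "n_mice_per_arm")
  expect_error(generator_config(doses = c(0, 7)), "doses")
  expect_error(generator_config(noise_sd = -1), "noise_sd")
})

test_that("basis library rows are normalized, non-negative, decorrelated", {
  lib <- generate_basis_library(wavenumber_grid(), 31, seed = 11)
  expect_equal(nrow(lib$basis_matrix), 31L)
  expect_true(all(lib$basis_matrix >= 0))
  areas <- apply(lib$basis_matrix, 1,
                 function(y) trapz_area(lib$grid, y))
  expect_true(all(abs(areas - 1) < 1e-9))

  lib5 <- generate_basis_library(wavenumber_grid(), 5, seed = 4,
                                 max_cosine = 0.90)
  H <- lib5$basis_matrix
  G <- H %*% t(H)                       # direct 5x5 Gram computation
  nrm <- sqrt(diag(G))
  C <- G / outer(nrm, nrm)
  diag(C) <- 0
  expect_lte(max(C), 0.90)
})

test_that("separability never decreases with effect size", {
  sep_ratio <- function(effect) {
    cfg <- generator_config(peaks = default_peak_table(effect),
                            n_mice_per_arm = 2, spectra_per_map = 5,
                            noise_sd = 0.02, seed = 31)
    ds <- generate_dataset(cfg)
    x0 <- ds$intensities[ds$meta$dose_gy == 0, ]
    x1 <- ds$intensities[ds$meta$dose_gy == 15, ]
    between <- sqrt(sum((colMeans(x0) - colMeans(x1))^2))
    pooled <- mean(c(apply(x0, 2, sd), apply(x1, 2, sd)))
    between / pooled
  }
  r <- vapply(c(0, 0.02, 0.05), sep_ratio, numeric(1))
  expect_true(all(diff(r) >= 0))
})

test_that("dataset and basis library round-trip through delimited text", {
  cfg <- generator_config(n_mice_per_arm = 1, spectra_per_map = 2,
                          sections_per_mouse = 2, seed = 8)
  ds <- generate_dataset(cfg)
  sp <- tempfile(fileext = ".tsv")
  mf <- tempfile(fileext = ".tsv")
  write_dataset(ds, sp, mf)
  back <- read_dataset(sp, mf)
  expect_equal(back$intensities, ds$intensities, tolerance = 1e-15)
  expect_equal(back$meta$mouse_id, ds$meta$mouse_id)
  expect_equal(back$grid$wavenumbers, ds$grid$wavenumbers)

  lib <- small_library(4, seed = 2)
  bf <- tempfile(fileext = ".tsv")
  write_basis_library(lib, bf)
  libb <- read_basis_library(bf)
  expect_equal(libb$basis_matrix, lib$basis_matrix, tolerance = 1e-15)
  expect_identical(libb$names, lib$names)
  unlink(c(sp, mf, bf))
})
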