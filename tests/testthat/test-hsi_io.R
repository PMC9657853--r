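# ENVI cube I/O and ROI spectrum extraction

test_that("ENVI write/read round-trips bit-exactly for both interleaves", {
  for (il in c("bil", "bip")) {
    cube <- random_cube(nr = 4, nc = 5, nb = 12, seed = 7)
    hdr <- file.path(withr::local_tempdir(), "cube.hdr")
    write_envi_cube(cube, hdr, interleave = il)
    back <- read_envi_cube(hdr)
    expect_identical(back$reflectance, cube$reflectance)
    expect_equal(back$wavelengths_nm, cube$wavelengths_nm)
    # mask is not serialized: reader defaults to all-TRUE
    expect_true(all(back$roi_mask))
    # re-serialization is stable (float32 is a fixed point)
    hdr2 <- file.path(withr::local_tempdir(), "cube2.hdr")
    write_envi_cube(back, hdr2, interleave = il)
    expect_identical(read_envi_cube(hdr2)$reflectance, cube$reflectance)
  }
})

test_that("the 462-band instrument grid survives the header verbatim", {
  wl <- seq(390.57, 1008.6, length.out = 462)
  cube <- spectral_cube(array(snap32(runif(2 * 2 * 462)), c(2, 2, 462)), wl)
  hdr <- file.path(withr::local_tempdir(), "full.hdr")
  write_envi_cube(cube, hdr)
  expect_true(any(grepl("^bands = 462$", readLines(hdr))))
  back <- read_envi_cube(hdr)
  expect_length(back$wavelengths_nm, 462L)
  expect_equal(back$wavelengths_nm, wl, tolerance = 1e-9)
})

test_that("malformed ENVI input raises classed I/O and format errors", {
  cube <- random_cube(nb = 10)
  dir <- withr::local_tempdir()
  hdr <- file.path(dir, "c.hdr")
  bin <- write_envi_cube(cube, hdr)
  # truncate the binary: error must name the expected size
  full <- readBin(bin, "raw", n = file.info(bin)$size)
  writeBin(full[-(1:4)], bin)
  err <- expect_error(read_envi_cube(hdr), class = "sl_io_error")
  expect_match(conditionMessage(err), as.character(4 * 4 * 4 * 10))

  writeLines(c("ENVI", "samples = 2", "lines = 2", "bands = 2",
               "data type = 4", "interleave = bil", "byte order = 0"),
             file.path(dir, "nowl.hdr"))
  writeBin(numeric(8), file.path(dir, "nowl.img"), size = 4)
  expect_error(read_envi_cube(file.path(dir, "nowl.hdr")),
               class = "sl_format_error")

  writeLines(c("ENVI", "samples = 2", "lines = 2", "bands = 2",
               "data type = 2", "interleave = bil",
               "wavelength = { 500, 600 }"), file.path(dir, "dt.hdr"))
  writeBin(numeric(8), file.path(dir, "dt.img"), size = 4)
  expect_error(read_envi_cube(file.path(dir, "dt.hdr")),
               class = "sl_format_error")

  expect_error(read_envi_cube(file.path(dir, "absent.hdr")),
               class = "sl_io_error")
  expect_error(write_envi_cube(cube, file.path(dir, "no", "deep.hdr")),
               class = "sl_io_error")
})

test_that("roi_mean_spectrum averages masked pixels per band", {
  # constant field: every masked pixel carries spectrum s
  s <- c(0.1, 0.5, 0.9)
  refl <- array(rep(s, each = 9), c(3, 3, 3))
  cube <- spectral_cube(refl, c(450, 550, 650))
  expect_equal(roi_mean_spectrum(cube)$values, s)

  # two masked pixels, band 0 values 0.2 / 0.4 -> 0.3
  refl2 <- array(0.7, c(2, 2, 3))
  refl2[1, 1, 1] <- 0.2; refl2[2, 2, 1] <- 0.4
  mask <- matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2)
  cube2 <- spectral_cube(refl2, c(450, 550, 650), mask)
  expect_equal(roi_mean_spectrum(cube2)$values[1], 0.3)

  # random 8x8 cube, 13-pixel mask: brute-force per-band pixel loop oracle
  set.seed(42)
  refl3 <- array(runif(8 * 8 * 5), c(8, 8, 5))
  mask3 <- matrix(FALSE, 8, 8)
  mask3[sample.int(64, 13)] <- TRUE
  cube3 <- spectral_cube(refl3, seq(450, 850, by = 100), mask3)
  got <- roi_mean_spectrum(cube3)$values
  for (b in 1:5) {
    acc <- 0; n <- 0
    for (i in 1:8) for (j in 1:8) if (mask3[i, j]) {
      acc <- acc + refl3[i, j, b]; n <- n + 1
    }
    expect_equal(got[b], acc / n, tolerance = 1e-12)
  }

  empty <- spectral_cube(refl3, seq(450, 850, by = 100),
                         matrix(FALSE, 8, 8))
  expect_error(roi_mean_spectrum(empty), class = "sl_precondition")
})

test_that("roi_mean_spectrum is linear and bounded by per-band extrema", {
  set.seed(9)
  wl <- seq(450, 850, by = 100)
  mask <- matrix(runif(36) > 0.5, 6, 6)
  a1 <- array(runif(180), c(6, 6, 5)); a2 <- array(runif(180), c(6, 6, 5))
  c1 <- spectral_cube(a1, wl, mask); c2 <- spectral_cube(a2, wl, mask)
  mix <- spectral_cube(2 * a1 + 0.5 * a2, wl, mask)
  expect_equal(roi_mean_spectrum(mix)$values,
               2 * roi_mean_spectrum(c1)$values +
                 0.5 * roi_mean_spectrum(c2)$values, tolerance = 1e-12)
  m <- roi_mean_spectrum(c1)$values
  for (b in 1:5) {
    px <- a1[, , b][mask]
    expect_gte(m[b], min(px)); expect_lte(m[b], max(px))
  }
})

test_that("NIR threshold mask separates leaf from dark background", {
  cfg <- synthetic_config("tub", noise_sd = 0)
  sp <- generate_leaf_spectrum(mean_nutrients(cfg), cfg)
  cube <- generate_cube(sp, c(12, 12), pixel_noise_sd = 0)
  expect_identical(nir_threshold_mask(cube, threshold = 0.1), cube$roi_mask)
})

test_that("sample tables validate and round-trip through CSV", {
  st <- generate_study(synthetic_config("nft", replicates = 1L))
  path <- file.path(withr::local_tempdir(), "tab.csv")
  write_sample_table(st$samples, path)
  back <- read_sample_table(path)
  expect_equal(back$NO3_ppm, st$samples$NO3_ppm, tolerance = 1e-9)
  expect_identical(back$cultivar, st$samples$cultivar)

  bad <- st$samples; bad$system[1] <- "field"
  expect_error(write_sample_table(bad, path), class = "sl_format_error")
  bad2 <- st$samples; bad2$applied_N_ppm[1] <- 75
  expect_error(write_sample_table(bad2, path), class = "sl_format_error")
  bad3 <- st$samples; bad3$pH[1] <- 15
  expect_error(write_sample_table(bad3, path), class = "sl_format_error")
})
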