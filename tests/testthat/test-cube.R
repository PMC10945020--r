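make_cube <- function(vals, wl = c(450, 550, 695)) {
  hypercube(array(vals, c(3, 4, length(wl))), wl, "raw")
}

test_that("reflectance calibration maps dark to 0, white to 1, midpoint to 0.5", {
  wl <- c(450, 550, 695)
  dark <- c(100, 110, 120); white <- c(4000, 4100, 4200)
  mk <- function(v) hypercube(
    array(rep(v, each = 12), c(3, 4, 3)), wl, "raw")
  at_white <- calibrate(mk(white), dark, white)
  expect_equal(unname(at_white$data), array(1, c(3, 4, 3)))
  expect_identical(at_white$kind, "reflectance")
  at_dark <- calibrate(mk(dark), dark, white)
  expect_equal(unname(at_dark$data), array(0, c(3, 4, 3)))
  at_mid <- calibrate(mk((dark + white) / 2), dark, white)
  expect_equal(unname(at_mid$data), array(0.5, c(3, 4, 3)))
})

test_that("calibration is affine per band and accepts full-cube references", {
  set.seed(1)
  wl <- c(450, 550, 695)
  dark <- c(100, 110, 120); white <- c(4000, 4100, 4200)
  r1 <- array(runif(36, 200, 3000), c(3, 4, 3))
  r3 <- array(rep(white, each = 12), c(3, 4, 3))
  alpha <- 0.3
  mixed <- alpha * r1 + (1 - alpha) * r3
  R1 <- calibrate(hypercube(r1, wl, "raw"), dark, white)$data
  Rmix <- calibrate(hypercube(mixed, wl, "raw"), dark, white)$data
  expect_equal(Rmix, alpha * R1 + (1 - alpha), tolerance = 1e-12)
  # broadcasting a cube-shaped reference gives the same result
  dk_cube <- hypercube(array(rep(dark, each = 12), c(3, 4, 3)), wl, "raw")
  wt_cube <- hypercube(r3, wl, "raw")
  R2 <- calibrate(hypercube(r1, wl, "raw"), dk_cube, wt_cube)$data
  expect_equal(R1, R2)
})

test_that("calibration refuses bands where white equals dark, naming them", {
  wl <- c(450, 550, 695)
  raw <- make_cube(500)
  expect_error(calibrate(raw, c(100, 110, 120), c(4000, 110, 4200)), "550")
})

test_that("foreground threshold at 695 nm is strictly greater than 0.075", {
  wl <- c(450, 550, 695)
  data <- array(0.5, c(2, 2, 3))
  data[1, 1, 3] <- 0.075    # exactly at threshold -> background
  data[1, 2, 3] <- 0.076
  data[2, 1, 3] <- 0.02
  cube <- hypercube(data, wl, "reflectance")
  mask <- segment_foreground(cube)
  expect_false(mask[1, 1])
  expect_true(mask[1, 2])
  expect_false(mask[2, 1])
  expect_error(segment_foreground(cube, wavelength_nm = 900), "outside")
})

test_that("a 150x10 rectangle partitions into 15 slices of 100 pixels, 10 columns each", {
  mask <- matrix(FALSE, 20, 160)
  mask[6:15, 6:155] <- TRUE
  labels <- partition_segments(mask)
  counts <- table(labels$segment[labels$segment > 0])
  expect_equal(unname(as.vector(counts)), rep(100, 15))
  for (s in 1:15) {
    cols <- unique(which(labels$segment == s, arr.ind = TRUE)[, 2])
    expect_length(cols, 10)
    expect_equal(sort(cols), min(cols):(min(cols) + 9))
  }
  # rotating the scene by 90 degrees transposes the partition exactly
  labels_t <- partition_segments(t(mask))
  expect_identical(labels_t$segment, t(labels$segment))
})

test_that("segments of an irregular blob are equal in area within one pixel", {
  scene <- generate_scene(small_config(seed = 8))
  mask <- scene$truth$mask > 0
  labels <- partition_segments(mask)
  for (id in seq_len(max(labels$sausage))) {
    counts <- table(labels$segment[labels$sausage == id])
    expect_length(counts, 15)
    expect_lte(max(counts) - min(counts), 1)
  }
  # no pixel lost or double-assigned
  expect_equal(sum(labels$segment > 0), sum(mask))
  expect_true(all((labels$segment > 0) == mask))
  expect_error(partition_segments(matrix(c(rep(TRUE, 5), rep(FALSE, 20)),
                                         5, 5)),
               "cannot partition")
})

test_that("component ids follow reading order so references align", {
  scene <- generate_scene(small_config(seed = 8))
  labels <- partition_segments(scene$truth$mask > 0)
  for (id in seq_len(max(labels$sausage)))
    expect_true(all(scene$truth$mask[labels$sausage == id] == id))
})

test_that("segment mean spectra average pixels and replicate the sausage reference", {
  # hand-built two-pixel segments: mean must be (a + b) / 2
  wl <- c(500, 600, 700)
  data <- array(0, c(2, 2, 3))
  data[1, 1, ] <- c(1, 2, 3); data[2, 1, ] <- c(3, 6, 9)
  data[1, 2, ] <- c(5, 5, 5); data[2, 2, ] <- c(7, 9, 11)
  cube <- hypercube(data, wl, "reflectance")
  labels <- structure(list(segment = matrix(c(1L, 1L, 2L, 2L), 2, 2),
                           sausage = matrix(1L, 2, 2), n_segments = 2L),
                      class = "segment_labels")
  tab <- extract_mean_spectra(cube, labels,
                              data.frame(sausage_id = 1,
                                         atp_log10_molL = -5.5))
  expect_equal(unname(tab$spectra[1, ]), c(2, 4, 6))
  expect_equal(unname(tab$spectra[2, ]), c(6, 7, 8))
  expect_equal(tab$meta$atp_log10_molL, c(-5.5, -5.5))
  expect_error(
    extract_mean_spectra(cube, labels,
                         data.frame(sausage_id = 2, atp_log10_molL = -5)),
    "missing")
})

test_that("zero-noise segment spectra equal the generating mixtures", {
  scene <- generate_scene(noise_free(n = 3))
  refl <- calibrate(scene$raw, scene$dark, scene$white)
  labels <- partition_segments(segment_foreground(refl))
  tab <- extract_mean_spectra(refl, labels, data.frame(
    sausage_id = 1:3, atp_log10_molL = scene$truth$atp_values))
  expect_equal(nrow(tab$spectra), 45)
  for (id in 1:3) {
    rows <- tab$meta$sausage_id == id
    expect_equal(tab$meta$atp_log10_molL[rows],
                 rep(scene$truth$atp_values[id], 15))
    err <- sweep(tab$spectra[rows, , drop = FALSE], 2,
                 scene$truth$mixture[id, ])
    expect_lt(max(abs(err)), 1e-10)
  }
})

test_that("spectra tables round-trip through CSV", {
  scene <- generate_scene(noise_free(n = 2))
  refl <- calibrate(scene$raw, scene$dark, scene$white)
  labels <- partition_segments(segment_foreground(refl))
  tab <- extract_mean_spectra(refl, labels, data.frame(
    sausage_id = 1:2, atp_log10_molL = scene$truth$atp_values))
  path <- tempfile(fileext = ".csv")
  write_spectra_csv(tab, path)
  back <- read_spectra_csv(path)
  expect_equal(back$wavelengths, tab$wavelengths)
  expect_equal(back$spectra, tab$spectra, ignore_attr = TRUE)
  expect_equal(back$meta$atp_log10_molL, tab$meta$atp_log10_molL)
})

test_that("RGB reconstruction picks the 600/550/450 nm planes and scales over foreground", {
  wl <- seq(400, 700, by = 50)
  data <- array(0.5, c(4, 4, length(wl)))
  cube <- hypercube(data, wl, "reflectance")
  grey <- reconstruct_rgb(cube, mask = matrix(TRUE, 4, 4))
  expect_equal(grey, array(0.5, c(4, 4, 3)))
  # mark the 600 nm plane: it must surface in the red channel only
  data[1, 1, which(wl == 600)] <- 1
  cube <- hypercube(data, wl, "reflectance")
  rgb <- reconstruct_rgb(cube, mask = matrix(TRUE, 4, 4))
  expect_equal(rgb[1, 1, 1], 1)
  expect_equal(rgb[2, 2, 1], 0)       # rest of red channel scaled to 0
  expect_equal(rgb[1, 1, 2], 0.5)     # green/blue channels still flat
  expect_error(reconstruct_rgb(hypercube(array(1, c(2, 2, 2)),
                                         c(500, 550), "reflectance"),
                               mask = matrix(TRUE, 2, 2)),
               "outside")
})

test_that("ENVI files round-trip a hypercube at float32 precision", {
  scene <- generate_scene(small_config(seed = 2, n = 2))
  path <- tempfile("cube_")
  write_envi(scene$raw, path)
  back <- read_envi(path)
  expect_equal(back$wavelengths, scene$raw$wavelengths)
  expect_identical(back$kind, "raw")
  expect_equal(back$data, scene$raw$data, tolerance = 1e-6)
})
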