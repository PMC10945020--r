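trained_on_scene <- function(config, spec = standard_chains()$snv_derivative_1,
                             max_components = 4, ...) {
  scene <- generate_scene(config)
  refl <- calibrate(scene$raw, scene$dark, scene$white)
  mask <- segment_foreground(refl)
  labels <- partition_segments(mask)
  tab <- extract_mean_spectra(refl, labels, data.frame(
    sausage_id = seq_len(config$n_sausages),
    atp_log10_molL = scene$truth$atp_values))
  res <- train_chain(tab, spec, max_components = max_components, ...)
  list(scene = scene, refl = refl, mask = mask, labels = labels,
       table = tab, res = res)
}

test_that("a spatially constant cube maps to the model's prediction of that spectrum", {
  set.seed(20)
  wl <- seq(400, 700, by = 10)
  spectrum <- runif(31, 0.3, 0.7)
  cube <- hypercube(array(rep(spectrum, each = 12), c(3, 4, 31)), wl,
                    "reflectance")
  X <- matrix(runif(8 * 31, 0.2, 0.8), 8, 31)
  y <- rnorm(8)
  fp <- chain_fit(pp_chain(), X, wl)
  model <- fit_plsr(X, y, 2)
  mask <- matrix(TRUE, 3, 4)
  map <- predict_pixels(cube, mask, fp, model)
  expected <- predict(model, rbind(spectrum))
  expect_equal(unname(as.vector(map$values)), rep(expected, 12),
               tolerance = 1e-10)
})

test_that("unfold/refold restores pixel coordinates exactly", {
  scene <- generate_scene(small_config(seed = 23, n = 2))
  refl <- calibrate(scene$raw, scene$dark, scene$white)
  mask <- segment_foreground(refl)
  X <- unfold_cube(refl)
  # spot-check the unfolding contract on a handful of pixels
  idx <- which(mask)[c(1, 57, 200)]
  for (i in idx) {
    r <- (i - 1) %% nrow(mask) + 1; cc <- (i - 1) %/% nrow(mask) + 1
    expect_equal(X[i, ], refl$data[r, cc, ])
  }
  tr <- trained_on_scene(small_config(seed = 23, n = 2))
  map <- predict_pixels(tr$refl, tr$mask, tr$res$preprocessor, tr$res$model)
  expect_true(all(is.na(map$values[!tr$mask])))
  expect_true(all(is.finite(map$values[tr$mask])))
})

test_that("zero-noise maps reproduce ground-truth ATP within 0.1 log units", {
  tr <- trained_on_scene(noise_free(seed = 24, n = 4))
  map <- predict_pixels(tr$refl, tr$mask, tr$res$preprocessor, tr$res$model)
  for (id in 1:4) {
    mu <- mean(map$values[tr$scene$truth$mask == id])
    expect_lt(abs(mu - tr$scene$truth$atp_values[id]), 0.1)
  }
})

test_that("segment means of pixel predictions match segment-spectrum predictions", {
  # linear chain (raw reflectance): equality up to numerical error
  tr <- trained_on_scene(small_config(seed = 25, n = 3),
                         spec = standard_chains()$raw_reflectance)
  map <- predict_pixels(tr$refl, tr$mask, tr$res$preprocessor, tr$res$model)
  seg_pred <- predict(tr$res$model,
                      chain_apply(tr$res$preprocessor, tr$table$spectra)$x)
  k <- 0
  for (id in 1:3) for (s in 1:15) {
    k <- k + 1
    pix <- tr$labels$sausage == id & tr$labels$segment == s
    expect_equal(mean(map$values[pix]), unname(seg_pred[k]),
                 tolerance = 1e-8)
  }
  # nonlinear chain (SNV): approximate agreement on a low-noise scene
  tr2 <- trained_on_scene(small_config(seed = 26, n = 3,
                                       scatter_multiplicative_sd = 0.01,
                                       baseline_offset_sd = 0.002,
                                       sample_scatter_sd = 0.02,
                                       sample_offset_sd = 0.001,
                                       sample_tilt_sd = 0.002,
                                       noise_sd = 0.001))
  map2 <- predict_pixels(tr2$refl, tr2$mask, tr2$res$preprocessor,
                         tr2$res$model)
  seg_pred2 <- predict(tr2$res$model,
                       chain_apply(tr2$res$preprocessor, tr2$table$spectra)$x)
  k <- 0
  for (id in 1:3) for (s in 1:15) {
    k <- k + 1
    pix <- tr2$labels$sausage == id & tr2$labels$segment == s
    expect_lt(abs(mean(map2$values[pix]) - seg_pred2[k]), 0.2)
  }
})

test_that("sausages at the treatment ATP extremes are numerically distinct on the map", {
  tr <- trained_on_scene(small_config(seed = 27, n = 2,
                                      atp_values = c(-8.66, -4.37)))
  map <- predict_pixels(tr$refl, tr$mask, tr$res$preprocessor, tr$res$model)
  m1 <- mean(map$values[tr$scene$truth$mask == 1])
  m2 <- mean(map$values[tr$scene$truth$mask == 2])
  expect_lt(m1, m2 - 2)      # clearly separated mean levels
  expect_lt(abs(m1 - (-8.66)), 1)
  expect_lt(abs(m2 - (-4.37)), 1)
})

test_that("degenerate pixels are dropped to background and counted", {
  set.seed(28)
  wl <- seq(400, 700, by = 10)
  data <- array(runif(12 * 31, 0.3, 0.7), c(3, 4, 31))
  data[2, 2, ] <- 0.5                   # constant spectrum breaks SNV
  cube <- hypercube(data, wl, "reflectance")
  X <- matrix(runif(8 * 31, 0.2, 0.8), 8, 31)
  fp <- chain_fit(pp_chain("snv"), X, wl)
  model <- fit_plsr(chain_apply(fp, X)$x, rnorm(8), 2)
  map <- predict_pixels(cube, matrix(TRUE, 3, 4), fp, model)
  expect_equal(map$n_degenerate, 1)
  expect_true(is.na(map$values[2, 2]))
})

test_that("rendered panels honour the colour-scale limits and clamp outliers", {
  values <- matrix(NA_real_, 4, 5)
  mask <- matrix(FALSE, 4, 5); mask[2:3, 2:4] <- TRUE
  values[mask] <- -6
  map <- structure(list(values = values, mask = mask, n_degenerate = 0L),
                   class = "atp_map")
  rgb <- array(0.5, c(4, 5, 3))
  path <- tempfile(fileext = ".png")
  out <- render_map(map, rgb, path, scale_limits = c(-9, -4))
  expect_true(file.exists(path))
  expect_equal(out$limits, c(-9, -4))
  # constant map: all foreground pixels share one colour
  fg_cols <- apply(out$panel[, 8:12, ], 3, function(ch) ch[mask])
  expect_equal(nrow(unique(fg_cols)), 1)
  # clamping: values beyond the limits render as the endpoint colours
  v2 <- values; v2[2, 2] <- -20; v2[3, 3] <- 3
  map2 <- structure(list(values = v2, mask = mask, n_degenerate = 0L),
                    class = "atp_map")
  out2 <- render_map(map2, rgb, tempfile(fileext = ".png"),
                     scale_limits = c(-9, -4))
  low_px <- out2$panel[2, 5 + 2 + 2, ]   # column offset into the map panel
  hi_px <- out2$panel[3, 5 + 2 + 3, ]
  bar <- out2$panel[, ncol(values) * 2 + 2 + 2 + 1 + 1, ]
  expect_equal(low_px, bar[4, ], tolerance = 1e-6)   # bottom of bar = min
  expect_equal(hi_px, bar[1, ], tolerance = 1e-6)    # top of bar = max
  expect_error(render_map(map, array(0.5, c(2, 2, 3)), tempfile()),
               "dimensions")
})
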