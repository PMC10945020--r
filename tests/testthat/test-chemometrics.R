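test_that("Kennard-Stone seeds with the extremes and matches the greedy oracle", {
  # 1-D example: the two most distant points form the calibration set
  X <- matrix(c(0, 1, 10), ncol = 1)
  sp <- kennard_stone(X, 2 / 3)
  expect_setequal(sp$calibration, c(1, 3))
  expect_equal(sp$prediction, 2)
  # rounding rule: n = 9 at 2/3 gives exactly 6 calibration rows
  X9 <- matrix(seq_len(9), ncol = 1)
  expect_length(kennard_stone(X9, 2 / 3)$calibration, 6)
  # full selection sequence equals the brute-force greedy oracle
  set.seed(10)
  for (rep in 1:3) {
    X20 <- matrix(rnorm(100), 20, 5)
    sel <- kennard_stone(X20, 2 / 3)$calibration
    expect_identical(sel, as.integer(ks_oracle(X20, length(sel))))
  }
  # duplicated rows resolve through the tie rule, not an error
  Xdup <- matrix(c(0, 0, 5, 5, 9), ncol = 1)
  expect_no_error(kennard_stone(Xdup, n_cal = 4))
})

test_that("PLSR fits a single latent direction exactly with one component", {
  set.seed(11)
  # spectra varying along one loading only, response linear in the score
  score <- rnorm(20)
  loading <- rnorm(10)
  X <- outer(score, loading) + 0.3
  y1 <- 0.5 * score + 2
  fit1 <- fit_plsr(X, y1, 1)
  expect_equal(predict(fit1, X), y1, tolerance = 1e-8)
  expect_equal(evaluate_model(fit1, X, y1)$r2, 1, tolerance = 1e-10)
})

test_that("full-rank PLSR equals ordinary least squares", {
  set.seed(12)
  X <- matrix(rnorm(60), 15, 4)
  y <- rnorm(15)
  fit <- fit_plsr(X, y, 4)
  ols <- lm(y ~ X)
  expect_equal(drop(predict(fit, X)), unname(fitted(ols)), tolerance = 1e-8)
})

test_that("PLSR coefficients are invariant to row permutation", {
  set.seed(13)
  X <- matrix(rnorm(80), 16, 5); y <- rnorm(16)
  fit <- fit_plsr(X, y, 3)
  perm <- sample(16)
  fit_p <- fit_plsr(X[perm, ], y[perm], 3)
  expect_equal(fit$b, fit_p$b, tolerance = 1e-10)
  expect_equal(fit$b0, fit_p$b0, tolerance = 1e-10)
})

test_that("requesting more components than the predictor rank errors", {
  set.seed(14)
  X <- matrix(rnorm(30), 10, 3)
  X <- cbind(X, X[, 1] + X[, 2])        # rank 3, 4 columns
  y <- rnorm(10)
  expect_error(fit_plsr(X, y, 4), "rank")
  expect_error(fit_plsr(X, y, 0), "ncomp")
})

test_that("leave-one-out cross-validation matches an explicit refit loop", {
  set.seed(15)
  X <- matrix(rnorm(24), 8, 3); y <- rnorm(8)
  cv <- cross_validate(X, y, 2)
  manual <- vapply(1:8, function(i)
    predict(fit_plsr(X[-i, ], y[-i], 2), X[i, , drop = FALSE]), numeric(1))
  expect_equal(cv$predictions, manual, tolerance = 1e-10)
  expect_equal(cv$rmsecv, sqrt(mean((y - manual)^2)), tolerance = 1e-12)
  # n = 4 produces exactly 4 held-out predictions
  expect_length(cross_validate(X[1:4, ], y[1:4], 1)$predictions, 4)
  # noise-free linear data cross-validates essentially perfectly
  yl <- drop(X %*% c(1, -2, 0.5))
  expect_lt(cross_validate(X, yl, 3)$rmsecv, 1e-8)
})

test_that("component selection minimises RMSECV with ties to fewer components", {
  set.seed(16)
  X <- matrix(rnorm(25 * 6), 25, 6)
  y <- drop(X %*% rnorm(6)) + rnorm(25, sd = 0.3)
  sel <- select_components(X, y, max_components = 5)
  # matches the exhaustive per-count oracle
  oracle <- vapply(1:5, function(k) cross_validate(X, y, k)$rmsecv,
                   numeric(1))
  expect_equal(sel$rmsecv, oracle, tolerance = 1e-10)
  expect_equal(sel$ncomp, which.min(oracle))
})

test_that("model metrics follow the subset-mean R2 and RMSE definitions", {
  set.seed(17)
  X <- matrix(rnorm(30), 10, 3)
  y <- drop(X %*% c(1, 2, -1))
  fit <- fit_plsr(X, y, 3)
  m <- evaluate_model(fit, X, y)
  expect_equal(m$r2, 1, tolerance = 1e-8)
  expect_equal(m$rmse, 0, tolerance = 1e-6)
  # a model predicting the subset mean scores exactly R2 = 0
  flat <- structure(list(b0 = mean(y), b = rep(0, 3)),
                    class = "plsr_model")
  expect_equal(evaluate_model(flat, X, y)$r2, 0)
  # spreadsheet-style hand computation on a tiny fixture
  yy <- c(1, 2, 4); yhat <- c(1.5, 2, 3)
  hand_r2 <- 1 - ((1 - 1.5)^2 + 0 + 1) / ((1 - 7 / 3)^2 + (2 - 7 / 3)^2 +
                                            (4 - 7 / 3)^2)
  toy <- structure(list(b0 = 0, b = 1), class = "plsr_model")
  m2 <- evaluate_model(toy, matrix(yhat, ncol = 1), yy)
  expect_equal(m2$r2, hand_r2, tolerance = 1e-12)
  expect_equal(m2$rmse, sqrt(mean((yy - yhat)^2)), tolerance = 1e-12)
  expect_error(evaluate_model(fit, X, rep(1, 10)), "zero variance")
})

test_that("calibration RMSE never increases with extra latent variables", {
  set.seed(18)
  X <- matrix(rnorm(30 * 8), 30, 8)
  y <- drop(X %*% rnorm(8)) + rnorm(30, sd = 0.5)
  rmse <- vapply(1:6, function(k)
    evaluate_model(fit_plsr(X, y, k), X, y)$rmse, numeric(1))
  expect_true(all(diff(rmse) <= 1e-10))
})

test_that("trained chains round-trip through the JSON artefact", {
  scene <- generate_scene(small_config(seed = 21))
  refl <- calibrate(scene$raw, scene$dark, scene$white)
  labels <- partition_segments(segment_foreground(refl))
  tab <- extract_mean_spectra(refl, labels, data.frame(
    sausage_id = 1:3, atp_log10_molL = scene$truth$atp_values))
  res <- train_chain(tab, standard_chains()$snv_derivative_1,
                     max_components = 4)
  path <- tempfile(fileext = ".json")
  write_model_json(res, path)
  back <- read_model_json(path)
  expect_equal(back$model$b, res$model$b, tolerance = 1e-12)
  expect_equal(back$model$b0, res$model$b0, tolerance = 1e-12)
  # the reloaded preprocessor + model predict pixels identically
  map1 <- predict_pixels(refl, segment_foreground(refl),
                         res$preprocessor, res$model)
  map2 <- predict_pixels(refl, segment_foreground(refl),
                         back$preprocessor, back$model)
  expect_equal(map1$values, map2$values, tolerance = 1e-10)
})
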