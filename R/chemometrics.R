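#' Kennard-Stone sample-set partitioning
#'
#' Deterministic max-min selection of calibration samples: seed with the
#' two most mutually distant rows (Euclidean), then repeatedly add the row
#' whose minimum distance to the selected set is largest, until
#' `round(fraction * n)` rows are selected. Ties are broken by the lowest
#' row index, so duplicated rows never cause an error.
#'
#' @param x numeric matrix of (pre-treated) spectra, one row per sample.
#' @param fraction calibration fraction of the data (default 2/3).
#' @param n_cal optional explicit calibration size, overriding `fraction`.
#' @return A `ks_split`: list with `calibration` (indices in selection
#'   order), `prediction` (remaining indices, ascending) and `metric`.
#' @export
kennard_stone <- function(x, fraction = 2 / 3, n_cal = NULL) {
  x <- rbind(x)
  n <- nrow(x)
  if (n < 3) stop("Kennard-Stone needs at least 3 samples")
  if (is.null(n_cal)) n_cal <- round(fraction * n)
  if (n_cal < 2 || n_cal >= n)
    stop("calibration size must be in [2, n-1], got ", n_cal)
  D <- as.matrix(stats::dist(x))
  if (!all(is.finite(D))) stop("non-finite distances between samples")
  # seed pair: maximum distance, ties by lowest (i, j)
  far <- which(D == max(D), arr.ind = TRUE)
  far <- far[far[, 1] < far[, 2], , drop = FALSE]
  far <- far[order(far[, 1], far[, 2]), , drop = FALSE]
  sel <- as.integer(far[1, ])
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  while (length(sel) < n_cal) {
    mind[sel] <- -Inf
    nxt <- as.integer(which.max(mind))   # first index on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
  }
  sel <- unname(sel)
  structure(list(calibration = sel,
                 prediction = setdiff(seq_len(n), sel),
                 metric = "euclidean"),
            class = "ks_split")
}

#' @export
print.ks_split <- function(x, ...) {
  cat(sprintf("<ks_split> %d calibration / %d prediction samples\n",
              length(x$calibration), length(x$prediction)))
  invisible(x)
}

#' Partial least squares regression (PLS1, NIPALS)
#'
#' Fits a latent-variable regression of a single response on spectra and
#' collapses it to a regression vector `b` and intercept `b0`, so that the
#' prediction for any spectrum `x` is `b0 + x %*% b` — the form applied
#' pixel-wise when building distribution maps.
#'
#' @param x numeric matrix of predictors (spectra), centred internally.
#' @param y numeric response vector.
#' @param ncomp number of latent variables; at most `min(n - 1, rank(X))`.
#' @return A `plsr_model`: list with `b0`, `b`, `ncomp`, the centring
#'   means, and the per-component weights/loadings.
#' @export
fit_plsr <- function(x, y, ncomp) {
  x <- rbind(x); y <- as.numeric(y)
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  x_mean <- colMeans(x); y_mean <- mean(y)
  Xc <- sweep(x, 2, x_mean); yc <- y - y_mean
  rank_x <- qr(Xc)$rank
  if (ncomp < 1 || ncomp > min(n - 1, p))
    stop("ncomp must be in [1, min(n-1, bands)]")
  if (ncomp > rank_x)
    stop("ncomp = ", ncomp, " exceeds the rank of the centred predictor ",
         "matrix (", rank_x, ")")
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp); q <- numeric(ncomp)
  Xd <- Xc; yd <- yc
  scale0 <- sqrt(sum(Xc^2) * sum(yc^2)) + 1e-300
  achieved <- 0L
  for (a in seq_len(ncomp)) {
    w <- drop(crossprod(Xd, yd))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12 * scale0) break     # residual covariance exhausted
    w <- w / nw
    t_score <- drop(Xd %*% w)
    tt <- sum(t_score^2)
    if (tt < 1e-24) break
    P[, a] <- drop(crossprod(Xd, t_score)) / tt
    q[a] <- sum(yd * t_score) / tt
    W[, a] <- w
    Xd <- Xd - tcrossprod(t_score, P[, a])
    yd <- yd - q[a] * t_score
    achieved <- a
  }
  if (achieved == 0L) stop("no extractable latent variable (X'y is zero)")
  W <- W[, seq_len(achieved), drop = FALSE]
  P <- P[, seq_len(achieved), drop = FALSE]
  q <- q[seq_len(achieved)]
  b <- drop(W %*% solve(crossprod(P, W), q))
  structure(list(b0 = y_mean - sum(x_mean * b), b = b, ncomp = achieved,
                 x_mean = x_mean, y_mean = y_mean,
                 weights = W, loadings = P, y_loadings = q),
            class = "plsr_model")
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("<plsr_model> %d latent variable(s), %d bands\n",
              x$ncomp, length(x$b)))
  invisible(x)
}

#' @param object a `plsr_model`.
#' @param newdata spectra matrix (or single spectrum) on the training band
#'   axis.
#' @param ... unused.
#' @rdname fit_plsr
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  newdata <- rbind(newdata)
  if (ncol(newdata) != length(object$b))
    stop("newdata has ", ncol(newdata), " bands; model expects ",
         length(object$b))
  unname(drop(object$b0 + newdata %*% object$b))
}

# Held-out predictions for every component count 1..kmax in one pass:
# NIPALS models are nested, so each fold is fitted once at kmax and the
# regression vector for smaller counts falls out of a triangular solve.
loo_predictions <- function(x, y, kmax) {
  x <- rbind(x); y <- as.numeric(y)
  n <- nrow(x)
  if (n < 3) stop("leave-one-out cross-validation needs n >= 3")
  pred <- matrix(NA_real_, n, kmax)
  for (i in seq_len(n)) {
    xi <- x[-i, , drop = FALSE]
    ki <- min(kmax, qr(scale(xi, scale = FALSE))$rank, n - 2)
    fit <- fit_plsr(xi, y[-i], ki)
    xc <- x[i, ] - fit$x_mean
    for (k in seq_len(kmax)) {
      kk <- min(k, fit$ncomp)
      Wk <- fit$weights[, seq_len(kk), drop = FALSE]
      Pk <- fit$loadings[, seq_len(kk), drop = FALSE]
      bk <- drop(Wk %*% solve(crossprod(Pk, Wk),
                              fit$y_loadings[seq_len(kk)]))
      pred[i, k] <- fit$y_mean + sum(xc * bk)
    }
  }
  pred
}

#' Leave-one-out ("full") cross-validation of PLSR
#'
#' Each sample is predicted by a model fitted on the remaining n - 1
#' samples with the same number of latent variables.
#'
#' @param x predictor matrix.
#' @param y response vector.
#' @param ncomp number of latent variables per fold.
#' @return List with `r2_cv`, `rmsecv` and the vector of held-out
#'   `predictions`.
#' @export
cross_validate <- function(x, y, ncomp) {
  y <- as.numeric(y)
  pred <- loo_predictions(x, y, ncomp)[, ncomp]
  list(r2_cv = 1 - sum((y - pred)^2) / sum((y - mean(y))^2),
       rmsecv = sqrt(mean((y - pred)^2)),
       predictions = pred)
}

#' Choose the number of latent variables by full cross-validation
#'
#' Returns the component count in `1..max_components` minimising RMSECV on
#' the calibration set; exact ties resolve to the smaller count.
#'
#' @param x calibration predictor matrix.
#' @param y calibration response.
#' @param max_components largest count tried; capped at
#'   `min(n - 2, rank(X))` so every leave-one-out fold stays fittable.
#' @return List with `ncomp` and the vector of `rmsecv` values tried.
#' @export
select_components <- function(x, y, max_components = NULL) {
  x <- rbind(x)
  n <- nrow(x)
  cap <- min(n - 2, qr(scale(x, scale = FALSE))$rank)
  if (is.null(max_components)) max_components <- min(20, ceiling(n / 3))
  max_components <- min(max_components, cap)
  if (max_components < 1) stop("no admissible number of components")
  pred <- loo_predictions(x, y, max_components)
  rmse <- sqrt(colMeans((as.numeric(y) - pred)^2))
  list(ncomp = which.min(rmse), rmsecv = rmse)
}

#' Goodness-of-fit metrics for a model on a data subset
#'
#' `R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2)` with the mean taken
#' over the evaluated subset, and `RMSE = sqrt(mean((y - yhat)^2))`, in
#' response units (here log10 mol/L ATP).
#'
#' @param model a `plsr_model`.
#' @param x spectra of the subset.
#' @param y reference values of the subset.
#' @return List with `r2` and `rmse`.
#' @export
evaluate_model <- function(model, x, y) {
  y <- as.numeric(y)
  if (stats::var(y) == 0)
    stop("response has zero variance on this subset; R2 undefined")
  yhat <- predict(model, x)
  list(r2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2),
       rmse = sqrt(mean((y - yhat)^2)))
}

#' Train and score one pre-treatment chain end to end
#'
#' Fits the chain on Kennard-Stone-selected calibration rows, selects the
#' latent-variable count by leave-one-out cross-validation, fits the final
#' PLSR model, and reports calibration / prediction / cross-validation
#' metrics. The Kennard-Stone split runs on the pre-treated spectra; with
#' `split_level = "sausage"` whole sausages (all their segments) move
#' together between the sets, avoiding replicate leakage.
#'
#' @param table a `spectra_table` (segments x bands with metadata).
#' @param spec a `pp_chain_spec`.
#' @param fraction calibration fraction (default 2/3).
#' @param max_components cap on latent variables (default
#'   `min(20, n/3)`).
#' @param split_level `"segment"` (default) or `"sausage"`.
#' @return A `chain_fit_result`: list with the fitted preprocessor, split,
#'   `plsr_model`, and a one-row `metrics` data.frame (r2_c, r2_cv, r2_p,
#'   rmsec, rmsecv, rmsep, ncomp).
#' @export
train_chain <- function(table, spec, fraction = 2 / 3,
                        max_components = NULL,
                        split_level = c("segment", "sausage")) {
  stopifnot(inherits(table, "spectra_table"))
  split_level <- match.arg(split_level)
  y <- table$meta$atp_log10_molL
  # the chain is fitted on the calibration subset; to choose that subset we
  # pre-treat provisionally on all rows, then refit cleanly on the split
  prov <- chain_fit(spec, table$spectra, table$wavelengths)
  Xp <- chain_apply(prov, table$spectra)$x
  if (split_level == "segment") {
    split <- kennard_stone(Xp, fraction)
    cal <- split$calibration; pred <- split$prediction
  } else {
    ids <- table$meta$sausage_id
    uid <- unique(ids)
    means <- t(vapply(uid, function(i) colMeans(Xp[ids == i, , drop = FALSE]),
                      numeric(ncol(Xp))))
    ks <- kennard_stone(means, fraction)
    cal <- which(ids %in% uid[ks$calibration])
    pred <- which(ids %in% uid[ks$prediction])
    split <- structure(list(calibration = cal, prediction = pred,
                            metric = "euclidean (sausage means)"),
                       class = "ks_split")
  }
  fitted_pp <- chain_fit(spec, table$spectra[cal, , drop = FALSE],
                         table$wavelengths)
  Xc <- chain_apply(fitted_pp, table$spectra[cal, , drop = FALSE])$x
  Xv <- chain_apply(fitted_pp, table$spectra[pred, , drop = FALSE])$x
  sel <- select_components(Xc, y[cal], max_components)
  model <- fit_plsr(Xc, y[cal], sel$ncomp)
  cv <- cross_validate(Xc, y[cal], sel$ncomp)
  mc <- evaluate_model(model, Xc, y[cal])
  mp <- evaluate_model(model, Xv, y[pred])
  metrics <- data.frame(chain = chain_label(spec), ncomp = sel$ncomp,
                        r2_c = mc$r2, rmsec = mc$rmse,
                        r2_p = mp$r2, rmsep = mp$rmse,
                        r2_cv = cv$r2_cv, rmsecv = cv$rmsecv)
  structure(list(preprocessor = fitted_pp, split = split, model = model,
                 metrics = metrics),
            class = "chain_fit_result")
}

#' @export
print.chain_fit_result <- function(x, ...) {
  cat("<chain_fit_result>\n")
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Save / load a trained model as a portable JSON artefact
#'
#' Serialises the pre-treatment chain, band axes, regression vector and
#' metrics so a map can be produced later without the training data.
#'
#' @param result a `chain_fit_result` from [train_chain()].
#' @param path JSON file path.
#' @return `write_model_json`: `path` invisibly; `read_model_json`: a list
#'   with `preprocessor` and `model` ready for [predict_pixels()].
#' @export
write_model_json <- function(result, path) {
  stopifnot(inherits(result, "chain_fit_result"))
  pp <- result$preprocessor
  obj <- list(
    steps = lapply(pp$spec$steps, function(s) {
      out <- list(name = s[[1]]); c(out, s[-1])
    }),
    state = lapply(pp$state, function(st)
      if (is.null(st)) NULL else list(reference = st$reference)),
    wavelengths_in = pp$wavelengths_in,
    wavelengths_out = pp$wavelengths_out,
    b0 = result$model$b0, b = result$model$b, ncomp = result$model$ncomp,
    metrics = result$metrics
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)   # keep lists as lists
  spec <- do.call(pp_chain, lapply(obj$steps, function(s) {
    step <- list(as.character(s$name))
    for (par in c("window", "degree", "order"))
      if (!is.null(s[[par]])) step[[par]] <- as.numeric(s[[par]])
    step
  }))
  state <- lapply(seq_along(spec$steps), function(i) {
    st <- if (i <= length(obj$state)) obj$state[[i]] else NULL
    if (is.null(st) || is.null(st$reference)) NULL
    else list(reference = as.numeric(unlist(st$reference)))
  })
  pp <- structure(list(spec = spec, state = state,
                       wavelengths_in = as.numeric(unlist(obj$wavelengths_in)),
                       wavelengths_out =
                         as.numeric(unlist(obj$wavelengths_out))),
                  class = "fitted_preprocessor")
  model <- structure(list(b0 = as.numeric(obj$b0),
                          b = as.numeric(unlist(obj$b)),
                          ncomp = as.integer(obj$ncomp)),
                     class = "plsr_model")
  list(preprocessor = pp, model = model, metrics = obj$metrics)
}
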