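#' Pixel-wise ATP distribution map
#'
#' Unfolds the masked pixels of a reflectance hypercube into a spectra
#' table, applies the fitted pre-treatment chain (state learned at
#' calibration time, never refitted) and the PLSR regression vector
#' (`b0 + x %*% b`) to every pixel, and refolds the predictions to image
#' coordinates. Pixels whose spectra trip a pre-treatment guard (e.g.
#' zero variance under SNV) are dropped to background and counted.
#'
#' @param cube a reflectance [hypercube] on the preprocessor's input band
#'   axis.
#' @param mask logical foreground matrix.
#' @param preprocessor a `fitted_preprocessor` from [chain_fit()].
#' @param model a `plsr_model`.
#' @return An `atp_map`: list with `values` (matrix of predicted ATP,
#'   `NA` off-foreground), `mask`, and `n_degenerate` (pixels dropped by
#'   pre-treatment guards).
#' @export
predict_pixels <- function(cube, mask, preprocessor, model) {
  stopifnot(inherits(cube, "hypercube"), is.matrix(mask),
            inherits(preprocessor, "fitted_preprocessor"),
            inherits(model, "plsr_model"))
  if (!any(mask)) stop("mask selects no pixels")
  d <- dim(cube$data)
  if (!identical(dim(mask), d[1:2]))
    stop("mask does not match the cube's spatial dimensions")
  if (length(cube$wavelengths) != length(preprocessor$wavelengths_in))
    stop("cube band axis does not match the preprocessor's input axis")
  if (length(preprocessor$wavelengths_out) != length(model$b))
    stop("preprocessor output axis (", length(preprocessor$wavelengths_out),
         " bands) does not match the regression vector (",
         length(model$b), ")")
  idx <- which(mask)                      # column-major pixel indices
  X <- unfold_cube(cube)[idx, , drop = FALSE]
  Xt <- chain_apply(preprocessor, X, na_degenerate = TRUE)$x
  ok <- stats::complete.cases(Xt)
  pred <- rep(NA_real_, length(idx))
  if (any(ok)) pred[ok] <- predict(model, Xt[ok, , drop = FALSE])
  values <- matrix(NA_real_, d[1], d[2])
  values[idx] <- pred
  structure(list(values = values, mask = mask,
                 n_degenerate = sum(!ok)),
            class = "atp_map")
}

#' @export
print.atp_map <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf(
    "<atp_map> %d foreground px, range [%.2f, %.2f] log10 mol/L (%d dropped)\n",
    sum(x$mask), min(v, na.rm = TRUE), max(v, na.rm = TRUE),
    x$n_degenerate))
  invisible(x)
}

# map a value matrix onto a blue->red linear colour scale; NA -> neutral grey
colourise_map <- function(values, limits) {
  ramp <- grDevices::colorRamp(c("#2c2cb4", "#28b4f0", "#50dc50",
                                 "#f0e442", "#d01c1c"))
  z <- (values - limits[1]) / (limits[2] - limits[1])
  z <- pmin(pmax(z, 0), 1)               # clamp out-of-range to endpoints
  flat <- z[!is.na(z)]
  rgbv <- ramp(flat) / 255
  out <- array(0.85, c(nrow(values), ncol(values), 3))  # neutral background
  for (ch in 1:3) {
    plane <- out[, , ch]
    plane[!is.na(z)] <- rgbv[, ch]
    out[, , ch] <- plane
  }
  out
}

#' Render an ATP map beside its RGB reconstruction
#'
#' Writes a PNG panel: the RGB reconstruction on the left, the
#' colour-scaled ATP map on the right, and a vertical colour bar. The
#' colour scale is linear; limits default to the range of the map's
#' foreground values (fix them, e.g. to the calibration ATP range, to
#' make maps comparable across sausages). Out-of-range pixels clamp to
#' the endpoint colours.
#'
#' @param map an `atp_map`.
#' @param rgb rows x cols x 3 array from [reconstruct_rgb()].
#' @param path output PNG path.
#' @param scale_limits optional `c(min, max)` for the colour scale.
#' @return Invisibly, a list with `file`, `limits` and the composed
#'   `panel` array.
#' @export
render_map <- function(map, rgb, path, scale_limits = NULL) {
  stopifnot(inherits(map, "atp_map"))
  d <- dim(map$values)
  if (!identical(dim(rgb)[1:2], d))
    stop("map and RGB image dimensions differ")
  fg <- map$values[!is.na(map$values)]
  if (!length(fg)) stop("map has no finite foreground values")
  limits <- if (is.null(scale_limits)) range(fg) else as.numeric(scale_limits)
  if (limits[2] <= limits[1]) limits[2] <- limits[1] + 1e-9
  coloured <- colourise_map(map$values, limits)
  gap <- array(1, c(d[1], 2, 3))
  bar_vals <- matrix(seq(limits[2], limits[1], length.out = d[1]), ncol = 1)
  bar <- colourise_map(bar_vals[, rep(1, 4), drop = FALSE], limits)
  panel <- array(NA_real_, c(d[1], d[2] * 2 + 10, 3))
  for (ch in 1:3)
    panel[, , ch] <- cbind(rgb[, , ch], gap[, , ch], coloured[, , ch],
                           gap[, , ch], bar[, , ch], gap[, , ch])
  png::writePNG(panel, path)
  invisible(list(file = path, limits = limits, panel = panel))
}
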