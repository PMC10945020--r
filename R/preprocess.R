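#' Spectral pre-treatments
#'
#' Row-wise transforms applied to a spectra matrix (one spectrum per row).
#' All transforms are row-independent, which is what makes them applicable
#' unchanged to single pixels when building distribution maps.
#'
#' @name pretreatments
NULL

#' Reflectance to absorbance
#'
#' `A = log10(1 / max(R, 1e-6))`. The clamp keeps the logarithm finite for
#' non-positive reflectance (possible after calibration of very dark
#' pixels); a clamped value maps to A = 6.
#'
#' @param x numeric matrix (rows = spectra) or vector.
#' @return Transformed matrix/vector of the same shape.
#' @export
absorbance <- function(x) log10(1 / pmax(x, 1e-6))

#' Standard normal variate
#'
#' Centres and scales each spectrum to mean 0 and standard deviation 1
#' (sample sd, denominator n - 1), removing per-spectrum additive offsets
#' and multiplicative scatter.
#'
#' @param x numeric matrix, one spectrum per row (>= 2 bands).
#' @param na_degenerate if `TRUE`, rows with zero variance become all-`NA`
#'   instead of raising an error (used for stray pixels in maps).
#' @return Matrix of the same shape.
#' @export
snv <- function(x, na_degenerate = FALSE) {
  x <- rbind(x)
  if (ncol(x) < 2) stop("SNV needs at least 2 bands")
  mu <- rowMeans(x)
  sd <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1))
  bad <- sd == 0
  if (any(bad) && !na_degenerate)
    stop("zero-variance spectrum in row(s) ",
         paste(which(bad), collapse = ", "), "; SNV undefined")
  out <- (x - mu) / ifelse(bad, NA_real_, sd)
  out
}

#' Multiplicative scatter correction
#'
#' `msc_reference()` learns the reference spectrum (band-wise mean of the
#' calibration spectra); `msc()` regresses each spectrum on the reference
#' by ordinary least squares, `x ~ a + b * ref`, and returns
#' `(x - a) / b`.
#'
#' @param x numeric matrix of calibration spectra (for `msc_reference`) or
#'   spectra to correct (for `msc`).
#' @param reference numeric reference spectrum from [msc_reference()].
#' @param na_degenerate if `TRUE`, rows whose slope `|b| < 1e-12` become
#'   all-`NA` instead of raising an error.
#' @return `msc_reference`: numeric vector; `msc`: corrected matrix.
#' @export
msc_reference <- function(x) colMeans(rbind(x))

#' @rdname msc_reference
#' @export
msc <- function(x, reference, na_degenerate = FALSE) {
  x <- rbind(x)
  if (ncol(x) != length(reference))
    stop("reference length does not match band count")
  rc <- reference - mean(reference)
  b <- drop(x %*% rc) / sum(rc^2) # slope of x on ref, shared denominator
  a <- rowMeans(x) - b * mean(reference)
  bad <- abs(b) < 1e-12
  if (any(bad) && !na_degenerate)
    stop("near-zero MSC slope in row(s) ", paste(which(bad), collapse = ", "))
  b[bad] <- NA_real_
  (x - a) / b
}

#' Min-max normalisation
#'
#' Scales each spectrum linearly to \[0, 1\].
#'
#' @param x numeric matrix, one spectrum per row.
#' @param na_degenerate if `TRUE`, constant rows become all-`NA` instead of
#'   raising an error.
#' @return Matrix of the same shape.
#' @export
minmax_normalise <- function(x, na_degenerate = FALSE) {
  x <- rbind(x)
  lo <- apply(x, 1, min); hi <- apply(x, 1, max)
  bad <- hi == lo
  if (any(bad) && !na_degenerate)
    stop("constant spectrum in row(s) ", paste(which(bad), collapse = ", "),
         "; min-max normalisation undefined")
  rng <- hi - lo; rng[bad] <- NA_real_
  (x - lo) / rng
}

# Smoothing matrix for Savitzky-Golay local polynomial fits. Edge bands use
# the truncated (one-sided) window, so a degree-d filter still reproduces
# degree-d polynomials exactly at every band.
sg_matrix <- function(p, window, degree) {
  if (window %% 2 == 0) stop("`window` must be odd")
  if (degree >= window) stop("`degree` must be smaller than `window`")
  if (p < window) stop("need at least `window` bands")
  h <- (window - 1) / 2
  S <- matrix(0, p, p)
  for (j in seq_len(p)) {
    idx <- max(1, j - h):min(p, j + h)
    A <- outer(idx - j, 0:degree, "^")
    w <- solve(crossprod(A), t(A))[1, ]   # fitted value at offset 0
    S[j, idx] <- w
  }
  S
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing over a sliding band window
#' (default: degree 2, five bands). Edge bands are fitted on the truncated
#' one-sided window rather than padded.
#'
#' @param x numeric matrix, one spectrum per row.
#' @param window odd window width in bands (default 5).
#' @param degree polynomial degree (default 2), less than `window`.
#' @return Smoothed matrix of the same shape.
#' @export
sg_smooth <- function(x, window = 5, degree = 2) {
  x <- rbind(x)
  x %*% t(sg_matrix(ncol(x), window, degree))
}

#' Increment derivative between consecutive bands
#'
#' The derivative used throughout is the plain increment between
#' consecutive bands (applied `order` times), computed after whatever
#' smoothing precedes it in the chain. The output loses `order` bands and
#' the wavelength axis moves to interval midpoints.
#'
#' @param x numeric matrix, one spectrum per row.
#' @param order 1 or 2.
#' @return Matrix with `ncol(x) - order` columns.
#' @export
increment_derivative <- function(x, order = 1) {
  x <- rbind(x)
  if (!order %in% 1:2) stop("`order` must be 1 or 2")
  if (ncol(x) < order + 1) stop("too few bands for derivative of order ", order)
  t(diff(t(x), differences = order))
}

#' Midpoint wavelength axis after differencing
#' @param wavelengths numeric axis.
#' @param order derivative order applied.
#' @return Numeric axis of length `length(wavelengths) - order`.
#' @export
derivative_wavelengths <- function(wavelengths, order = 1) {
  for (i in seq_len(order))
    wavelengths <- (wavelengths[-1] + wavelengths[-length(wavelengths)]) / 2
  wavelengths
}

# ---- ordered pre-treatment chains -----------------------------------------

#' Build a pre-treatment chain specification
#'
#' A chain is an ordered list of steps, each a name from
#' `absorbance`, `snv`, `msc`, `normalise`, `sg_smooth`, `derivative`
#' with optional parameters (`window`/`degree` for `sg_smooth`, `order`
#' for `derivative`). MSC is the only stateful step: its reference
#' spectrum is learned from the calibration subset by [chain_fit()] and
#' then applied unchanged everywhere else (no train/test leakage).
#'
#' @param ... step definitions: bare strings (`"snv"`) or lists
#'   (`list("sg_smooth", window = 5, degree = 2)`).
#' @return An object of class `pp_chain_spec`.
#' @examples
#' pp_chain("absorbance", "snv",
#'          list("sg_smooth", window = 5, degree = 2),
#'          list("derivative", order = 1))
#' @export
pp_chain <- function(...) {
  steps <- lapply(list(...), function(s) {
    if (is.character(s)) s <- list(s)
    names(s)[1] <- ""
    known <- c("absorbance", "snv", "msc", "normalise", "sg_smooth",
               "derivative")
    if (!s[[1]] %in% known)
      stop("unknown pre-treatment step: ", s[[1]])
    s
  })
  structure(list(steps = steps), class = "pp_chain_spec")
}

#' @export
print.pp_chain_spec <- function(x, ...) {
  cat("<pp_chain>", chain_label(x), "\n")
  invisible(x)
}

#' Human-readable label for a chain
#' @param spec a `pp_chain_spec`.
#' @return A single string such as `"absorbance + snv + derivative(1)"`.
#' @export
chain_label <- function(spec) {
  if (!length(spec$steps)) return("identity")
  paste(vapply(spec$steps, function(s) {
    extras <- s[-1]
    if (length(extras))
      paste0(s[[1]], "(", paste(unlist(extras), collapse = ","), ")")
    else s[[1]]
  }, character(1)), collapse = " + ")
}

#' Fit a pre-treatment chain on calibration spectra
#'
#' Runs the chain over the calibration set, learning the state of any
#' stateful step (the MSC reference) from the calibration rows only, and
#' records the band-axis bookkeeping under derivatives.
#'
#' @param spec a `pp_chain_spec` from [pp_chain()].
#' @param x calibration spectra matrix (rows = spectra).
#' @param wavelengths band axis of `x` in nm.
#' @return A `fitted_preprocessor`: the spec plus learned state and the
#'   output wavelength axis.
#' @export
chain_fit <- function(spec, x, wavelengths) {
  stopifnot(inherits(spec, "pp_chain_spec"))
  x <- rbind(x)
  if (ncol(x) != length(wavelengths))
    stop("wavelength axis does not match spectra")
  state <- vector("list", length(spec$steps))
  wl <- wavelengths
  for (i in seq_along(spec$steps)) {
    s <- spec$steps[[i]]
    if (s[[1]] == "msc") state[[i]] <- list(reference = msc_reference(x))
    res <- apply_step(s, x, wl, state[[i]], na_degenerate = FALSE, step = i)
    x <- res$x; wl <- res$wavelengths
  }
  structure(list(spec = spec, state = state,
                 wavelengths_in = wavelengths, wavelengths_out = wl),
            class = "fitted_preprocessor")
}

#' @export
print.fitted_preprocessor <- function(x, ...) {
  cat(sprintf("<fitted_preprocessor> %s (%d -> %d bands)\n",
              chain_label(x$spec), length(x$wavelengths_in),
              length(x$wavelengths_out)))
  invisible(x)
}

apply_step <- function(s, x, wl, state, na_degenerate, step) {
  out <- tryCatch(switch(s[[1]],
    absorbance = list(x = absorbance(x), wavelengths = wl),
    snv        = list(x = snv(x, na_degenerate), wavelengths = wl),
    msc        = list(x = msc(x, state$reference, na_degenerate),
                      wavelengths = wl),
    normalise  = list(x = minmax_normalise(x, na_degenerate),
                      wavelengths = wl),
    sg_smooth  = list(x = sg_smooth(x,
                        window = if (is.null(s$window)) 5 else s$window,
                        degree = if (is.null(s$degree)) 2 else s$degree),
                      wavelengths = wl),
    derivative = {
      ord <- if (is.null(s$order)) 1 else s$order
      list(x = increment_derivative(x, ord),
           wavelengths = derivative_wavelengths(wl, ord))
    }),
    error = function(e)
      stop("pre-treatment step ", step, " (", s[[1]], "): ",
           conditionMessage(e), call. = FALSE))
  out
}

#' Apply a fitted pre-treatment chain to new spectra
#'
#' Applies the chain, using state learned at fit time; never refits. With
#' `na_degenerate = TRUE` rows that hit a guard (zero variance under SNV,
#' constant under normalisation, near-zero MSC slope) propagate as `NA`
#' rows instead of stopping — the mode used for pixel-wise prediction.
#'
#' @param fitted a `fitted_preprocessor` from [chain_fit()].
#' @param x spectra matrix on the fit-time input band axis.
#' @param na_degenerate see Description.
#' @return List with `x` (transformed matrix) and `wavelengths`.
#' @export
chain_apply <- function(fitted, x, na_degenerate = FALSE) {
  stopifnot(inherits(fitted, "fitted_preprocessor"))
  x <- rbind(x)
  if (ncol(x) != length(fitted$wavelengths_in))
    stop("input has ", ncol(x), " bands; chain was fitted on ",
         length(fitted$wavelengths_in))
  wl <- fitted$wavelengths_in
  for (i in seq_along(fitted$spec$steps)) {
    res <- apply_step(fitted$spec$steps[[i]], x, wl, fitted$state[[i]],
                      na_degenerate, step = i)
    x <- res$x; wl <- res$wavelengths
  }
  list(x = x, wavelengths = wl)
}

#' The nine pre-treatment chains of the standard sweep
#'
#' The standard comparison runs PLSR under nine treatments: raw
#' reflectance; raw absorbance; then, on absorbance spectra, MSC, 1st
#' derivative, SNV, 2nd derivative, min-max normalisation, SNV + 1st
#' derivative, and 1st derivative + SNV. Derivatives are preceded by
#' degree-2, five-band Savitzky-Golay smoothing.
#'
#' @return Named list of `pp_chain_spec` objects.
#' @export
standard_chains <- function() {
  sg <- list("sg_smooth", window = 5, degree = 2)
  list(
    "raw_reflectance"      = pp_chain(),
    "raw_absorbance"       = pp_chain("absorbance"),
    "msc"                  = pp_chain("absorbance", "msc"),
    "derivative_1"         = pp_chain("absorbance", sg,
                                      list("derivative", order = 1)),
    "snv"                  = pp_chain("absorbance", "snv"),
    "derivative_2"         = pp_chain("absorbance", sg,
                                      list("derivative", order = 2)),
    "normalisation"        = pp_chain("absorbance", "normalise"),
    "snv_derivative_1"     = pp_chain("absorbance", "snv", sg,
                                      list("derivative", order = 1)),
    "derivative_1_snv"     = pp_chain("absorbance", sg,
                                      list("derivative", order = 1), "snv")
  )
}
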