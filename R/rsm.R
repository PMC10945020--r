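#' Casing-treatment factors of the central composite design
#'
#' The five factors of the 2^(5-1) central composite design, with the
#' centre and step of each factor's coded metric: cube points sit at
#' coded +/-1 (= centre +/- step), axial points at +/-2, centre points at 0.
#'
#' @return data.frame with columns `name`, `unit`, `centre`, `step`.
#' @export
ccd_factors <- function() {
  data.frame(
    name = c("soy_lecithin", "soy_oil", "duration", "lactic_acid",
             "orange_extract"),
    unit = c("g/100 g water", "g/100 g water", "min", "ul/15 g NaCl", "g"),
    centre = c(3.33, 1.875, 75, 292.5, 0.28),
    step = c(1.11, 0.625, 15, 22.5, 0.145)
  )
}

#' Canonical term labels of the 21-term quadratic model
#'
#' Order: constant, five linear terms, five squares, ten two-way
#' interactions (the order in which sequential ANOVA sums of squares are
#' attributed).
#'
#' @param factors factor table as from [ccd_factors()].
#' @return Character vector of length 21.
#' @export
quadratic_terms <- function(factors = ccd_factors()) {
  nm <- factors$name
  inter <- utils::combn(nm, 2, FUN = function(p) paste(p, collapse = ":"))
  c("constant", nm, paste0(nm, "^2"), inter)
}

# 21-column model matrix from a coded n x 5 matrix, canonical term order
coded_model_matrix <- function(coded) {
  coded <- as.matrix(coded)
  stopifnot(ncol(coded) == 5)
  ij <- utils::combn(5, 2)
  inter <- vapply(seq_len(ncol(ij)),
                  function(k) coded[, ij[1, k]] * coded[, ij[2, k]],
                  numeric(nrow(coded)))
  cbind(1, coded, coded^2, matrix(inter, nrow = nrow(coded)))
}

#' Evaluate a coded-unit quadratic polynomial
#'
#' Evaluates `y = b0 + sum(bi ui) + sum(bii ui^2) + sum(bij ui uj)` at
#' coded factor settings, with coefficients in the canonical
#' [quadratic_terms()] order. This is the shared prediction path for
#' fitted models, published coefficient tables, and the synthetic response
#' generator.
#'
#' @param coefficients numeric vector of 21 coefficients.
#' @param coded numeric matrix (or single row) of coded settings, 5
#'   columns.
#' @return Numeric vector of predictions.
#' @export
evaluate_coded_quadratic <- function(coefficients, coded) {
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != 21)
    stop("expected 21 coefficients (constant, 5 linear, 5 square, ",
         "10 interaction), got ", length(coefficients))
  unname(drop(coded_model_matrix(rbind(coded)) %*% coefficients))
}

#' The packaged casing-treatment design and measured ATP table
#'
#' The 32-run central composite design (16 cube, 10 axial, 6 replicated
#' centre runs) over the five casing-treatment factors, with the measured
#' ATP response (log10 mol/L, mean of quadruplicate bioluminescence
#' assays), its standard deviation, and the published model predictions.
#'
#' @return data.frame with one row per treatment run.
#' @export
atp_ccd <- function() {
  utils::read.csv(system.file("extdata", "ccd_atp_table.csv",
                              package = "hsiATP"))
}

#' Published coded coefficients of the ATP response-surface model
#'
#' The 21 coded-unit coefficients and their standard errors as reported
#' for the fitted ATP model; used as ground truth in simulation-recovery
#' studies and as input to the coded prediction path.
#'
#' @return data.frame with columns `term`, `coefficient`, `se`.
#' @export
published_coefficients <- function() {
  utils::read.csv(system.file("extdata", "ccd_coded_coefficients.csv",
                              package = "hsiATP"))
}

#' Assemble a central composite design from an uncoded run table
#'
#' Coded levels are inferred from the design structure: each factor is
#' centred and scaled by its coded step and snapped to the nearest of
#' {-2, -1, 0, 1, 2}. This is deliberate — printed run tables round the
#' uncoded levels (the orange-extract +1 level appears as 0.41/0.42/0.43),
#' so rounding back from the printed values would misassign levels. A run
#' further than 0.25 coded units from a canonical level is rejected.
#'
#' @param table data.frame with one column per factor (named as in
#'   `factors$name`) and a response column.
#' @param response name of the response column (default `"atp_measured"`).
#' @param factors factor table as from [ccd_factors()].
#' @return A `ccd_design`: list with `coded` (n x 5 matrix), `uncoded`,
#'   `response`, `factors`, and `point_type` (cube/axial/centre per run).
#' @export
build_design <- function(table, response = "atp_measured",
                         factors = ccd_factors()) {
  missing_cols <- setdiff(c(factors$name, response), names(table))
  if (length(missing_cols))
    stop("run table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  uncoded <- as.matrix(table[factors$name])
  z <- sweep(sweep(uncoded, 2, factors$centre), 2, factors$step, "/")
  coded <- round(z)
  off <- abs(z - coded)
  if (any(coded < -2 | coded > 2) || any(off > 0.25)) {
    bad <- which(rowSums(off > 0.25 | abs(coded) > 2) > 0)
    stop("run(s) ", paste(bad, collapse = ", "),
         " do not sit on a canonical coded level (-2..2)")
  }
  n_axial <- rowSums(abs(coded) == 2)
  point_type <- ifelse(rowSums(coded != 0) == 0, "centre",
                       ifelse(n_axial == 1 & rowSums(coded != 0) == 1,
                              "axial", "cube"))
  if (any(point_type == "cube" & apply(abs(coded) > 1, 1, any)))
    stop("run with mixed axial/cube coded levels found")
  structure(list(coded = coded, uncoded = uncoded,
                 response = as.numeric(table[[response]]),
                 factors = factors, point_type = point_type),
            class = "ccd_design")
}

#' @export
print.ccd_design <- function(x, ...) {
  cat(sprintf("<ccd_design> %d runs: %d cube, %d axial, %d centre\n",
              nrow(x$coded), sum(x$point_type == "cube"),
              sum(x$point_type == "axial"), sum(x$point_type == "centre")))
  invisible(x)
}

#' Fit the 21-term quadratic response-surface model
#'
#' Ordinary least squares of the response on the full quadratic model in
#' coded units (constant, linear, square and two-way interaction terms).
#' Standard errors come from `sigma^2 (X'X)^-1` with `sigma^2 = SSE /
#' (n - 21)`; p-values are two-sided from the t distribution on the error
#' degrees of freedom. Uncoded coefficients are obtained by algebraic
#' back-transformation and give identical predictions.
#'
#' @param design a `ccd_design` from [build_design()].
#' @return An `rsm_model`: list with `coefficients` (data.frame: term,
#'   coefficient, se, t, p), `uncoded_coefficients`, `fitted`,
#'   `residuals`, `sigma2`, `df_residual`, `r2`, the underlying `lm` fit
#'   and the `design`.
#' @export
fit_quadratic <- function(design) {
  stopifnot(inherits(design, "ccd_design"))
  C <- design$coded; y <- design$response
  n <- nrow(C)
  if (n <= 21) stop("need more than 21 runs to fit the quadratic model")
  d <- data.frame(a = C[, 1], b = C[, 2], cc = C[, 3], dd = C[, 4],
                  e = C[, 5], y = y)
  form <- y ~ a + b + cc + dd + e +
    I(a^2) + I(b^2) + I(cc^2) + I(dd^2) + I(e^2) +
    a:b + a:cc + a:dd + a:e + b:cc + b:dd + b:e + cc:dd + cc:e + dd:e
  fit <- stats::lm(form, data = d)
  sm <- summary(fit)
  co <- sm$coefficients
  terms <- quadratic_terms(design$factors)
  coefficients <- data.frame(term = terms,
                             coefficient = unname(co[, 1]),
                             se = unname(co[, 2]),
                             t = unname(co[, 3]),
                             p = unname(co[, 4]))
  b <- co[, 1]
  centre <- design$factors$centre; step <- design$factors$step
  # back-transform coded coefficients to natural units:
  # u_i = (x_i - c_i) / s_i
  lin <- b[2:6]; sq <- b[7:11]; ij <- utils::combn(5, 2)
  inter <- b[12:21]
  B_int <- inter / (step[ij[1, ]] * step[ij[2, ]])
  B_sq <- sq / step^2
  B_lin <- lin / step - 2 * sq * centre / step^2
  for (k in seq_len(ncol(ij))) {
    i <- ij[1, k]; j <- ij[2, k]
    B_lin[i] <- B_lin[i] - inter[k] * centre[j] / (step[i] * step[j])
    B_lin[j] <- B_lin[j] - inter[k] * centre[i] / (step[i] * step[j])
  }
  B0 <- b[1] - sum(lin * centre / step) + sum(sq * centre^2 / step^2) +
    sum(inter * centre[ij[1, ]] * centre[ij[2, ]] /
          (step[ij[1, ]] * step[ij[2, ]]))
  uncoded <- data.frame(term = terms,
                        coefficient = c(B0, B_lin, B_sq, B_int))
  sse <- sum(stats::residuals(fit)^2)
  sst <- sum((y - mean(y))^2)
  structure(list(coefficients = coefficients,
                 uncoded_coefficients = uncoded,
                 fitted = stats::fitted(fit),
                 residuals = stats::residuals(fit),
                 sigma2 = sse / fit$df.residual,
                 df_residual = fit$df.residual,
                 r2 = 1 - sse / sst,
                 lm_fit = fit, design = design),
            class = "rsm_model")
}

#' @export
print.rsm_model <- function(x, ...) {
  cat(sprintf("<rsm_model> 21-term coded quadratic, R2 = %.4f (df %d)\n",
              x$r2, x$df_residual))
  invisible(x)
}

#' Predict ATP from the response-surface model
#'
#' @param object an `rsm_model`.
#' @param newdata matrix or data.frame of factor settings, 5 columns in
#'   factor order (or named after the factors).
#' @param coded whether `newdata` is in coded units (default `TRUE`); if
#'   `FALSE`, natural units are converted using the design's centres and
#'   steps.
#' @param ... unused.
#' @return Numeric vector of predicted ATP (log10 mol/L). Settings outside
#'   +/-2 coded units trigger a warning (extrapolation).
#' @export
predict.rsm_model <- function(object, newdata, coded = TRUE, ...) {
  fnames <- object$design$factors$name
  newdata <- rbind(newdata)
  if (!is.null(colnames(newdata)) && all(fnames %in% colnames(newdata)))
    newdata <- newdata[, fnames, drop = FALSE]
  newdata <- matrix(as.numeric(newdata), ncol = 5)
  cd <- if (coded) newdata
  else sweep(sweep(newdata, 2, object$design$factors$centre), 2,
             object$design$factors$step, "/")
  if (any(abs(cd) > 2))
    warning("settings outside +/-2 coded units; extrapolating")
  evaluate_coded_quadratic(object$coefficients$coefficient, cd)
}

#' Sequential ANOVA with lack-of-fit decomposition
#'
#' Type-I (sequential) sums of squares with terms entered in the canonical
#' order (linear, squares, interactions); contribution is each row's share
#' of the total SS. Adjusted SS per 1-df term is `t^2 * MSE`. The residual
#' is split into lack of fit and pure error, the latter being the
#' within-replicate SS of the centre points, and lack of fit is F-tested
#' against pure error.
#'
#' @param model an `rsm_model`.
#' @return An `anova_table` data.frame with columns `term`, `df`,
#'   `seq_ss`, `contribution`, `adj_ss`, `p`; rows for the 20 model terms
#'   followed by Error, Lack-of-fit, Pure error and Total. Attributes
#'   `r2`, `sse`, `sst`, `lof_p`.
#' @export
rsm_anova <- function(model) {
  stopifnot(inherits(model, "rsm_model"))
  an <- stats::anova(model$lm_fit)
  k <- nrow(an) - 1L                       # model terms, Residuals last
  seq_ss <- an[seq_len(k), "Sum Sq"]
  sse <- an[k + 1L, "Sum Sq"]
  df_err <- an[k + 1L, "Df"]
  sst <- sum(an[, "Sum Sq"])
  co <- model$coefficients[-1, ]           # drop constant
  adj_ss <- co$t^2 * model$sigma2
  y <- model$design$response
  centre <- model$design$point_type == "centre"
  n_centre <- sum(centre)
  rows <- data.frame(term = co$term, df = an[seq_len(k), "Df"],
                     seq_ss = seq_ss,
                     contribution = 100 * seq_ss / sst,
                     adj_ss = adj_ss, p = co$p)
  lof_p <- NA_real_
  if (n_centre >= 2) {
    pe <- sum((y[centre] - mean(y[centre]))^2)
    df_pe <- n_centre - 1L
    lof <- sse - pe
    df_lof <- df_err - df_pe
    f_lof <- (lof / df_lof) / (pe / df_pe)
    lof_p <- stats::pf(f_lof, df_lof, df_pe, lower.tail = FALSE)
    extra <- data.frame(
      term = c("Error", "Lack-of-fit", "Pure error", "Total"),
      df = c(df_err, df_lof, df_pe, nrow(model$design$coded) - 1L),
      seq_ss = c(sse, lof, pe, sst),
      contribution = c(100 * sse / sst, 100 * lof / sst, 100 * pe / sst,
                       100),
      adj_ss = c(sse, lof, pe, NA),
      p = c(NA, lof_p, NA, NA))
  } else {
    warning("no replicated centre points; lack-of-fit row omitted")
    extra <- data.frame(
      term = c("Error", "Total"),
      df = c(df_err, nrow(model$design$coded) - 1L),
      seq_ss = c(sse, sst),
      contribution = c(100 * sse / sst, 100),
      adj_ss = c(sse, NA), p = c(NA, NA))
  }
  out <- rbind(rows, extra)
  rownames(out) <- NULL
  structure(out, class = c("anova_table", "data.frame"),
            r2 = model$r2, sse = sse, sst = sst, lof_p = lof_p)
}

#' Prediction grid over two factors for surface/contour plots
#'
#' Evaluates the fitted quadratic on a rectangular grid spanning +/-2
#' coded units of two factors, with the remaining factors held at their
#' centre (coded 0).
#'
#' @param model an `rsm_model`.
#' @param factor_pair character vector of two distinct factor names
#'   (default soy lecithin vs orange extract).
#' @param n grid resolution per axis (default 50).
#' @return List with `x`, `y` (coded grid axes), `x_natural`,
#'   `y_natural`, and `z` (n x n prediction matrix, rows indexed by `x`).
#' @export
surface_grid <- function(model,
                         factor_pair = c("soy_lecithin", "orange_extract"),
                         n = 50) {
  fnames <- model$design$factors$name
  idx <- match(factor_pair, fnames)
  if (any(is.na(idx))) stop("unknown factor in `factor_pair`")
  if (idx[1] == idx[2]) stop("`factor_pair` must name two distinct factors")
  ax <- seq(-2, 2, length.out = n)
  grid <- expand.grid(x = ax, y = ax)
  pts <- matrix(0, nrow(grid), 5)
  pts[, idx[1]] <- grid$x; pts[, idx[2]] <- grid$y
  z <- matrix(predict(model, pts), n, n)   # rows follow x
  fa <- model$design$factors
  list(x = ax, y = ax,
       x_natural = fa$centre[idx[1]] + ax * fa$step[idx[1]],
       y_natural = fa$centre[idx[2]] + ax * fa$step[idx[2]],
       z = z, factor_pair = factor_pair)
}

#' Standardised effects (Pareto ranking)
#'
#' Ranks the 20 non-constant terms by the absolute t statistic
#' `|coefficient| / SE`, with the two-sided critical value
#' `t(0.975, df_error)` as the significance reference line.
#'
#' @param model an `rsm_model`.
#' @return data.frame with columns `term`, `effect_t` (absolute t,
#'   descending), `finite` (FALSE where SE underflowed, e.g. a noise-free
#'   synthetic fit); attribute `critical`.
#' @export
pareto_effects <- function(model) {
  co <- model$coefficients[-1, ]
  t_abs <- abs(co$coefficient / co$se)
  # an (essentially) zero residual makes every SE underflow: flag rather
  # than rank meaningless ratios
  finite <- is.finite(t_abs) & co$se > 1e-10
  t_abs[!finite] <- Inf
  out <- data.frame(term = co$term, effect_t = t_abs, finite = finite)
  out <- out[order(-out$effect_t), ]
  rownames(out) <- NULL
  structure(out,
            critical = stats::qt(0.975, model$df_residual))
}
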