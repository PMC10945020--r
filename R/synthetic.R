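#' Configuration for a synthetic hyperspectral scene
#'
#' Describes a simulated acquisition: image geometry, a 151-band
#' wavelength grid (350-1100 nm in 5 nm steps by default), the number of
#' sausages and their reference ATP values, and three noise magnitudes in
#' reflectance units. The defaults model the corruption structure of a
#' push-broom acquisition under halogen lighting where multiplicative
#' scatter dominates, with two scales: a per-sausage scatter factor
#' (surface curvature and placement differ between samples; sd 0.10) and a
#' per-pixel factor (local surface texture; sd 0.04), plus additive
#' baseline offsets and a smooth spectral tilt at the sausage scale, and
#' small band-wise noise.
#'
#' @param n_sausages number of sausages in the scene.
#' @param atp_values reference ATP per sausage (log10 mol/L); defaults to
#'   an even spread over the observed treatment range -9.33..-4.37.
#' @param image_height,image_width scene size in pixels; by default the
#'   height grows with the number of sausages.
#' @param n_bands number of spectral bands (default 151).
#' @param wavelength_start,wavelength_step wavelength grid in nm (default
#'   350 nm start, 5 nm step).
#' @param scatter_multiplicative_sd sd of the per-pixel multiplicative
#'   scatter factor (1 + m).
#' @param baseline_offset_sd sd of the per-pixel additive offset.
#' @param sample_scatter_sd sd of the per-sausage multiplicative scatter
#'   factor; this component does not average out over segments, so it is
#'   the corruption that scatter-correcting pre-treatments must remove.
#' @param sample_offset_sd sd of the per-sausage additive offset.
#' @param sample_tilt_sd sd of a per-sausage additive baseline slope
#'   across the wavelength axis (scatter varies smoothly with
#'   wavelength); the tilt basis is linear in wavelength, scaled to
#'   \[-1, 1\] over the axis.
#' @param noise_sd sd of independent band-wise noise.
#' @param seed integer seed; fully determines the generated scene.
#' @return A `scene_config` list.
#' @export
scene_config <- function(n_sausages = 12,
                         atp_values = seq(-9.33, -4.37,
                                          length.out = n_sausages),
                         image_height = 22 * n_sausages + 6,
                         image_width = 120,
                         n_bands = 151,
                         wavelength_start = 350, wavelength_step = 5,
                         scatter_multiplicative_sd = 0.04,
                         baseline_offset_sd = 0.01,
                         sample_scatter_sd = 0.10,
                         sample_offset_sd = 0.005,
                         sample_tilt_sd = 0.01,
                         noise_sd = 0.005,
                         seed = 1L) {
  if (n_bands < 3) stop("`n_bands` must be at least 3")
  if (wavelength_step <= 0) stop("`wavelength_step` must be positive")
  if (length(atp_values) != n_sausages)
    stop("`atp_values` must have one value per sausage")
  if (any(c(scatter_multiplicative_sd, baseline_offset_sd,
            sample_scatter_sd, sample_offset_sd, sample_tilt_sd,
            noise_sd) < 0))
    stop("noise standard deviations must be non-negative")
  structure(list(n_sausages = n_sausages, atp_values = atp_values,
                 image_height = image_height, image_width = image_width,
                 n_bands = n_bands, wavelength_start = wavelength_start,
                 wavelength_step = wavelength_step,
                 scatter_multiplicative_sd = scatter_multiplicative_sd,
                 baseline_offset_sd = baseline_offset_sd,
                 sample_scatter_sd = sample_scatter_sd,
                 sample_offset_sd = sample_offset_sd,
                 sample_tilt_sd = sample_tilt_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "scene_config")
}

# Two smooth endmember reflectance spectra (Gaussians on a baseline with
# peaks in 350-450 and 600-750 nm, the most ATP-variable regions); the
# high-ATP endmember lies above the low-ATP one everywhere, reproducing
# the observation that higher ATP gives higher reflectance.
scene_endmembers <- function(wavelengths) {
  low <- 0.18 + 0.16 * exp(-((wavelengths - 390) / 45)^2) +
    0.24 * exp(-((wavelengths - 670) / 60)^2)
  high <- 0.35 + 0.18 * exp(-((wavelengths - 430) / 60)^2) +
    0.22 * exp(-((wavelengths - 710) / 70)^2)
  rbind(low = low, high = high)
}

# truncate normal draws at +/- 3.9 sd so separation guards are hard bounds
rnorm_trunc <- function(n, sd) {
  if (sd == 0) return(numeric(n))
  pmin(pmax(stats::rnorm(n, 0, sd), -3.9 * sd), 3.9 * sd)
}

#' Generate a synthetic scene with known ground truth
#'
#' Builds a raw hypercube plus dark and white reference frames such that
#' dark/white calibration recovers a known reflectance field. Sausages are
#' axis-aligned ellipses on a dark background (reflectance 0.02); the
#' foreground reflectance of each sausage is a convex mixture of two
#' endmember spectra weighted by its ATP value rescaled to \[0, 1\] over
#' the scene's ATP range, then corrupted by multiplicative scatter factors
#' (1 + m) at the sausage and pixel scales, additive offsets at the same
#' two scales, and band-wise noise (all draws truncated at 3.9 sd). The
#' raw cube is `dark + R * (white - dark)`.
#'
#' Configurations whose noise could push background and foreground across
#' the 0.075 reflectance threshold at 695 nm are rejected, so threshold
#' segmentation recovers the ground-truth mask exactly by construction.
#'
#' @param config a [scene_config()].
#' @return List with `raw` (raw [hypercube]), `dark`, `white` (per-band
#'   reference vectors), and `truth`: list with `mask` (integer sausage id
#'   per pixel, 0 = background), `atp` (per-pixel ATP, `NA` on
#'   background), `reflectance` (the noisy reflectance embedded in the raw
#'   cube), `mixture` (noise-free mixture reflectance per sausage, rows =
#'   sausages), `endmembers`, `weights` and `atp_values`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  wl <- config$wavelength_start +
    config$wavelength_step * (seq_len(config$n_bands) - 1)
  em <- scene_endmembers(wl)
  b695 <- which.min(abs(wl - 695))
  if (abs(wl[b695] - 695) > config$wavelength_step)
    stop("wavelength grid does not cover the 695 nm segmentation band")
  atp <- config$atp_values
  rng <- range(atp)
  w <- if (diff(rng) > 0) (atp - rng[1]) / diff(rng) else rep(0.5, length(atp))
  mixture <- outer(1 - w, em["low", ]) + outer(w, em["high", ])
  bg_level <- 0.02
  thr <- 0.075
  fg_min_695 <- min(mixture[, b695])
  guard <- 3.9
  tilt_basis <- 2 * (wl - min(wl)) / (max(wl) - min(wl)) - 1
  mult_sd <- config$scatter_multiplicative_sd + config$sample_scatter_sd
  add_sd <- config$baseline_offset_sd + config$sample_offset_sd +
    config$sample_tilt_sd * abs(tilt_basis[b695])
  if (fg_min_695 * (1 - guard * mult_sd) -
      guard * add_sd - guard * config$noise_sd <= thr)
    stop("noise configuration lets foreground cross the 0.075 threshold ",
         "at 695 nm; scene would be unusable")
  if (bg_level + guard * config$noise_sd >= thr)
    stop("noise configuration lets background cross the 0.075 threshold ",
         "at 695 nm; scene would be unusable")

  h <- config$image_height; wd <- config$image_width; p <- config$n_bands
  mask <- matrix(0L, h, wd)
  slot <- h / config$n_sausages
  semi_b <- min(8, floor(slot / 2) - 2)
  if (semi_b < 2) stop("image too small for the requested number of sausages")
  semi_a <- min(50, floor(wd / 2) - 5)
  rows <- matrix(rep(seq_len(h), wd), h, wd)
  cols <- matrix(rep(seq_len(wd), each = h), h, wd)
  for (s in seq_len(config$n_sausages)) {
    cy <- (s - 0.5) * slot + 0.5
    cx <- wd / 2
    inside <- ((rows - cy) / semi_b)^2 + ((cols - cx) / semi_a)^2 <= 1
    mask[inside] <- s
  }

  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  set.seed(config$seed)

  refl <- array(bg_level, c(h, wd, p))
  atp_map <- matrix(NA_real_, h, wd)
  for (s in seq_len(config$n_sausages)) {
    pix <- which(mask == s)
    n_pix <- length(pix)
    m_samp <- rnorm_trunc(1L, config$sample_scatter_sd)
    o_samp <- rnorm_trunc(1L, config$sample_offset_sd)
    tilt <- rnorm_trunc(1L, config$sample_tilt_sd)
    m <- rnorm_trunc(n_pix, config$scatter_multiplicative_sd)
    off <- rnorm_trunc(n_pix, config$baseline_offset_sd)
    base <- mixture[s, ]
    scale_px <- (1 + m_samp) * (1 + m)
    shift_px <- o_samp + off
    for (b in seq_len(p)) {
      plane <- refl[, , b]
      plane[pix] <- base[b] * scale_px + shift_px + tilt * tilt_basis[b]
      refl[, , b] <- plane
    }
    atp_map[pix] <- atp[s]
  }
  if (config$noise_sd > 0)
    refl <- refl + array(rnorm_trunc(h * wd * p, config$noise_sd),
                         c(h, wd, p))

  dark <- 120 + 0.01 * (wl - 350)
  white <- 3200 + 600 * exp(-((wl - 550) / 250)^2)
  raw_data <- array(0, c(h, wd, p))
  for (b in seq_len(p))
    raw_data[, , b] <- dark[b] + refl[, , b] * (white[b] - dark[b])
  list(raw = hypercube(raw_data, wl, "raw"),
       dark = dark, white = white,
       truth = list(mask = mask, atp = atp_map, reflectance = refl,
                    mixture = mixture, endmembers = em, weights = w,
                    atp_values = atp))
}

#' Simulate responses from a central composite design
#'
#' Evaluates a known coded-unit quadratic at every run of the design and
#' adds Gaussian noise — the ground-truth generator for
#' coefficient-recovery studies of the response-surface fit.
#'
#' @param design a `ccd_design` from [build_design()].
#' @param coefficients 21 coded coefficients in [quadratic_terms()] order.
#' @param noise_sd response noise sd (same units as the response).
#' @param seed integer seed.
#' @return Numeric vector of simulated responses, one per run.
#' @export
generate_ccd_responses <- function(design, coefficients, noise_sd = 0,
                                   seed = 1L) {
  stopifnot(inherits(design, "ccd_design"))
  mu <- evaluate_coded_quadratic(coefficients, design$coded)
  old_seed <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, .GlobalEnv), add = TRUE)
  set.seed(as.integer(seed))
  mu + stats::rnorm(length(mu), 0, noise_sd)
}

#' Write a generated scene to disk
#'
#' Writes the raw cube as an ENVI pair, the dark/white references and
#' ground-truth table as CSV — the plain-text interchange layout used by
#' the pipeline.
#'
#' @param scene output of [generate_scene()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(scene, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_envi(scene$raw, file.path(dir, "raw"))
  utils::write.csv(
    data.frame(wavelength = scene$raw$wavelengths,
               dark = scene$dark, white = scene$white),
    file.path(dir, "references.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(sausage_id = seq_along(scene$truth$atp_values),
               atp_log10_molL = scene$truth$atp_values),
    file.path(dir, "ground_truth.csv"), row.names = FALSE)
  utils::write.csv(
    data.frame(row = rep(seq_len(nrow(scene$truth$mask)),
                         ncol(scene$truth$mask)),
               col = rep(seq_len(ncol(scene$truth$mask)),
                         each = nrow(scene$truth$mask)),
               sausage = as.vector(scene$truth$mask)),
    file.path(dir, "mask.csv"), row.names = FALSE)
  invisible(dir)
}
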