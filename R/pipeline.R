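#' Configuration for an end-to-end run
#'
#' Collects everything a reproducible run needs: either a synthetic scene
#' configuration or paths to an ENVI cube with reference frames and a
#' per-sausage ATP table, the pre-treatment chains to sweep, the
#' Kennard-Stone fraction, the latent-variable cap, and one global seed
#' that fans out to per-stage derived seeds.
#'
#' @param scene a [scene_config()] for simulated input, or `NULL` when
#'   `input_dir` points at on-disk data.
#' @param input_dir directory holding `raw.hdr`/`raw.dat`,
#'   `references.csv` and `ground_truth.csv` (the [write_scene()] layout);
#'   ignored when `scene` is given.
#' @param chains named list of `pp_chain_spec`s to sweep (default
#'   [standard_chains()]).
#' @param ks_fraction Kennard-Stone calibration fraction (default 2/3).
#' @param max_components latent-variable cap (default `min(20, n/3)`).
#' @param split_level `"segment"` or `"sausage"` (see [train_chain()]).
#' @param seed global integer seed.
#' @param out_dir output directory for metrics, models, maps and logs.
#' @return A `run_config` list.
#' @export
run_config <- function(scene = NULL, input_dir = NULL,
                       chains = standard_chains(),
                       ks_fraction = 2 / 3, max_components = NULL,
                       split_level = "segment",
                       seed = 1L, out_dir = tempfile("hsiatp_run_")) {
  if (is.null(scene) && is.null(input_dir))
    stop("provide either a scene configuration or an input directory")
  structure(list(scene = scene, input_dir = input_dir, chains = chains,
                 ks_fraction = ks_fraction, max_components = max_components,
                 split_level = split_level, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

read_scene_dir <- function(dir) {
  needed <- c("raw.hdr", "raw.dat", "references.csv", "ground_truth.csv")
  missing_f <- needed[!file.exists(file.path(dir, needed))]
  if (length(missing_f))
    stop("input directory ", dir, " is missing: ",
         paste(missing_f, collapse = ", "))
  refs <- utils::read.csv(file.path(dir, "references.csv"))
  list(raw = read_envi(file.path(dir, "raw")),
       dark = refs$dark, white = refs$white,
       reference = utils::read.csv(file.path(dir, "ground_truth.csv")))
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> calibrate -> segment -> partition -> extract ->
#' sweep the pre-treatment chains through Kennard-Stone + PLSR -> pick the
#' best chain by prediction R^2 -> distribution map of the scene with the
#' best model. Every artefact lands in `config$out_dir`: `metrics.csv`
#' (one row per chain, best chain flagged), `best_model.json`,
#' `spectra.csv`, `atp_map.csv` and `atp_map.png`, `config.json` and
#' `run.log`. Deterministic given the config seed.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `metrics` (data.frame), `best` (name of
#'   the winning chain), `results` (per-chain `chain_fit_result`s), `map`
#'   (the best chain's `atp_map`) and `out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  t0 <- Sys.time()
  log_lines <- character()
  say <- function(fmt, ...) {
    line <- sprintf("[%6.2fs] %s", as.numeric(Sys.time() - t0, units = "secs"),
                    sprintf(fmt, ...))
    log_lines <<- c(log_lines, line)
  }
  stage <- function(name, expr) {
    say("stage %s: start", name)
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say("stage %s: done", name)
    out
  }

  input <- stage("input", {
    if (!is.null(config$scene)) {
      sc <- config$scene
      sc$seed <- config$seed + 1L    # derived per-stage seed
      scene <- generate_scene(sc)
      list(raw = scene$raw, dark = scene$dark, white = scene$white,
           reference = data.frame(
             sausage_id = seq_along(scene$truth$atp_values),
             atp_log10_molL = scene$truth$atp_values),
           truth = scene$truth)
    } else read_scene_dir(config$input_dir)
  })
  refl <- stage("calibrate", calibrate(input$raw, input$dark, input$white))
  mask <- stage("segment", segment_foreground(refl))
  labels <- stage("partition", partition_segments(mask))
  table <- stage("extract",
                 extract_mean_spectra(refl, labels, input$reference))

  results <- stage("train", {
    lapply(config$chains, function(spec)
      train_chain(table, spec, fraction = config$ks_fraction,
                  max_components = config$max_components,
                  split_level = config$split_level))
  })
  metrics <- do.call(rbind, lapply(results, `[[`, "metrics"))
  metrics <- cbind(treatment = names(config$chains), metrics)
  metrics$best <- seq_len(nrow(metrics)) == which.max(metrics$r2_p)
  rownames(metrics) <- NULL
  best <- names(config$chains)[which.max(metrics$r2_p)]
  say("best chain by prediction R^2: %s", best)

  map <- stage("map", {
    res <- results[[best]]
    predict_pixels(refl, mask, res$preprocessor, res$model)
  })

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- config$out_dir
  utils::write.csv(metrics, file.path(out, "metrics.csv"),
                   row.names = FALSE)
  write_spectra_csv(table, file.path(out, "spectra.csv"))
  write_model_json(results[[best]], file.path(out, "best_model.json"))
  utils::write.csv(
    data.frame(row = rep(seq_len(nrow(map$values)), ncol(map$values)),
               col = rep(seq_len(ncol(map$values)),
                         each = nrow(map$values)),
               atp = as.vector(map$values)),
    file.path(out, "atp_map.csv"), row.names = FALSE)
  rgb <- reconstruct_rgb(refl, mask)
  atp_rng <- range(table$meta$atp_log10_molL)
  render_map(map, rgb, file.path(out, "atp_map.png"),
             scale_limits = atp_rng)
  cfg <- config
  cfg$chains <- lapply(config$chains, chain_label)
  cfg$scene <- unclass(cfg$scene)
  jsonlite::write_json(unclass(cfg), file.path(out, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       force = TRUE)
  say("artefacts written to %s", out)
  writeLines(log_lines, file.path(out, "run.log"))
  invisible(list(metrics = metrics, best = best, results = results,
                 map = map, out_dir = out))
}
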