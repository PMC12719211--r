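#' Pipeline configuration
#'
#' Validated configuration for [run_pipeline()]. Unknown keys (at the top
#' level or inside a section) are rejected, and a seed is mandatory.
#'
#' @param seed Master RNG seed (mandatory).
#' @param n_samples Number of simulated samples.
#' @param mode `"HSI"` or `"HMI"`.
#' @param blanch_times Blanching design, minutes.
#' @param assay_cv Relative SD of the simulated reference assays.
#' @param sample_variation Per-sample lognormal baseline variation (SD).
#' @param scene Named list of [scene_config()] overrides.
#' @param preprocessing List: `snv` (logical), `floor` (calibration floor).
#' @param model List: `targets`, `k_max`, `n_folds`, `train_fraction`.
#' @param mapping List: `clip_policy`, `colormap`, `write_maps` (logical).
#' @param output List: `write_cubes` (logical; raw ENVI cubes are large and
#'   off by default).
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = NULL,
                            n_samples = 60,
                            mode = "HSI",
                            blanch_times = c(0, 2, 4, 6, 10),
                            assay_cv = 0.05,
                            sample_variation = 0.15,
                            scene = list(),
                            preprocessing = list(),
                            model = list(),
                            mapping = list(),
                            output = list()) {
  if (is.null(seed) || !is.finite(seed)) stopf("pipeline config requires a seed")
  check_keys <- function(x, allowed, where) {
    bad <- setdiff(names(x), allowed)
    if (length(bad)) {
      stopf("unknown %s key(s): %s", where, paste(bad, collapse = ", "))
    }
  }
  check_keys(scene, setdiff(names(formals(scene_config)), "seed"), "scene")
  check_keys(preprocessing, c("snv", "floor"), "preprocessing")
  check_keys(model, c("targets", "k_max", "n_folds", "train_fraction"), "model")
  check_keys(mapping, c("clip_policy", "colormap", "write_maps"), "mapping")
  check_keys(output, "write_cubes", "output")
  pre <- utils::modifyList(list(snv = FALSE, floor = 1e-6), preprocessing)
  mod <- utils::modifyList(list(targets = c("ppo", "tpc"), k_max = 15,
                                n_folds = 10, train_fraction = 0.75), model)
  mp <- utils::modifyList(list(clip_policy = "train_range",
                               colormap = "viridis", write_maps = TRUE), mapping)
  out <- utils::modifyList(list(write_cubes = FALSE), output)
  structure(list(seed = as.integer(seed), n_samples = n_samples, mode = mode,
                 blanch_times = blanch_times, assay_cv = assay_cv,
                 sample_variation = sample_variation, scene = scene,
                 preprocessing = pre, model = mod, mapping = mp,
                 output = out),
            class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML (`.yaml`/`.yml`) or JSON configuration file whose keys
#'   follow the `pipeline_config()` arguments.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  lst <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  check <- setdiff(names(lst), names(formals(pipeline_config)))
  if (length(check)) stopf("unknown config key(s): %s", paste(check, collapse = ", "))
  do.call(pipeline_config, lst)
}

#' Run the end-to-end analysis pipeline
#'
#' Simulate (or extend to ingest) -> calibrate -> ROI -> extract -> train
#' both targets -> evaluate -> map, writing a reference CSV, wide-format
#' spectra CSV, model/report JSONs, beta-coefficient CSVs, per-blanch-time
#' distribution maps, and a run manifest with per-output MD5 checksums.
#' Deterministic for a fixed configuration and seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if absent).
#' @return The manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list()
  outputs <- character(0)
  stage <- function(name, expr) {
    message(sprintf("[blanchspec] stage %-10s seed=%d", name, config$seed))
    tryCatch(expr, error = function(e) {
      stopf("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }
  record <- function(name, files) {
    stages[[name]] <<- list(name = name, outputs = basename(files),
                            md5 = unname(tools::md5sum(files)))
    outputs <<- c(outputs, files)
  }

  scn_cfg <- do.call(scene_config,
                     c(config$scene, list(mode = config$mode, seed = config$seed)))
  ds <- stage("simulate", {
    simulate_dataset(n_samples = config$n_samples, mode = config$mode,
                     blanch_times = config$blanch_times,
                     assay_cv = config$assay_cv,
                     sample_variation = config$sample_variation,
                     seed = config$seed, config = scn_cfg,
                     snv = config$preprocessing$snv)
  })
  ref_path <- file.path(out_dir, "reference.csv")
  ref <- data.frame(sample_id = ds$sample_ids,
                    blanch_time_min = ds$metadata$blanch_time_min,
                    ppo_u_per_g = ds$y$ppo,
                    tpc_mg_per_100g = ds$y$tpc)
  utils::write.csv(ref, ref_path, row.names = FALSE)
  spec_path <- file.path(out_dir, "spectra_wide.csv")
  wide <- data.frame(sample_id = ds$sample_ids, ds$x)
  names(wide)[-1] <- sprintf("nm%g", as.numeric(ds$grid))
  utils::write.csv(wide, spec_path, row.names = FALSE)
  record("simulate", c(ref_path, spec_path))

  reports <- list()
  train_files <- character(0)
  for (target in config$model$targets) {
    rep <- stage(paste0("train_", target), {
      plsr_calibrate(ds, target = target,
                     k_max = config$model$k_max,
                     n_folds = config$model$n_folds,
                     train_fraction = config$model$train_fraction,
                     seed = config$seed)
    })
    reports[[target]] <- rep
    model_path <- file.path(out_dir, sprintf("model_%s.json", target))
    write_plsr_json(rep$model, model_path)
    report_path <- file.path(out_dir, sprintf("report_%s.json", target))
    jsonlite::write_json(
      list(target = target,
           r2_c = rep$r2_c, rmsec = rep$rmsec,
           r2_cv = rep$r2_cv, rmsecv = rep$rmsecv,
           r2_p = rep$r2_p, rmsep = rep$rmsep,
           rpd = rep$rpd, n_components = rep$n_components,
           seed = config$seed),
      report_path, auto_unbox = TRUE, digits = NA)
    beta_path <- file.path(out_dir, sprintf("beta_%s.csv", target))
    utils::write.csv(data.frame(band_nm = as.numeric(ds$grid),
                                beta = rep$model$beta),
                     beta_path, row.names = FALSE)
    train_files <- c(train_files, model_path, report_path, beta_path)
  }
  record("train", train_files)

  if (isTRUE(config$mapping$write_maps)) {
    map_files <- stage("map", {
      map_dir <- file.path(out_dir, "maps")
      dir.create(map_dir, showWarnings = FALSE)
      files <- character(0)
      for (i in seq_along(config$blanch_times)) {
        cfg_i <- scn_cfg
        cfg_i$blanch_time_min <- config$blanch_times[i]
        cfg_i$seed <- derive_seed(config$seed, "scene", i)
        sc <- simulate_scene(cfg_i)
        cube <- calibrate_reflectance(sc$frames, config$preprocessing$floor)
        mask <- pca_roi(cube)
        for (target in config$model$targets) {
          m <- predict_map(cube, mask, reports[[target]]$model,
                           clip_policy = config$mapping$clip_policy)
          png_path <- file.path(map_dir, sprintf("map_%s_t%02d.png", target,
                                                 config$blanch_times[i]))
          render_map(m, png_path, config$mapping$colormap)
          files <- c(files, png_path, paste0(png_path, ".json"))
        }
        if (isTRUE(config$output$write_cubes)) {
          base <- file.path(out_dir, sprintf("cube_t%02d", config$blanch_times[i]))
          write_envi(cube, base)
          files <- c(files, paste0(base, ".hdr"), paste0(base, ".dat"))
        }
      }
      files
    })
    record("map", map_files)
  }

  manifest <- list(
    package = "blanchspec",
    version = as.character(utils::packageVersion("blanchspec")),
    seed = config$seed,
    config = unclass(config),
    stages = stages,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}
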