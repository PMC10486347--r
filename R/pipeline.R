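# Whole-study orchestration: simulate -> (preprocess) -> select -> fit the
# model battery -> evaluate -> rank -> (visualize), from one config.

#' Default pipeline configuration
#'
#' Returns the full default config as a named list; [run_pipeline()] accepts
#' a partial list (or a YAML file path) and fills the rest from here. One
#' global `seed` deterministically derives every stage seed.
#'
#' @param seed Global seed.
#' @return Named list of pipeline settings.
#' @export
default_pipeline_config <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(n_samples = 120, n_bands = 600,
                    regions = "dorsal", n_latent = 4,
                    noise_sd_spectral = 0.5, noise_sd_texture = 0.05,
                    nonlinearity = 0, two_cluster = FALSE),
    sg = list(window = 11, polyorder = 2),
    selection = NULL, # or list(method="rc", mode="peak_threshold", param=0.1)
    indicators = texture_indicators(),
    models = model_kinds(),
    model_opts = list(n_intervals = 10, combo_size = 2, grid_points = 20,
                      hidden_size = 10, cv_folds = 5),
    split = list(fraction = 0.75, strategy = "random"),
    visualize = NULL # or list(rows = 48, cols = 48)
  )
}

merge_config <- function(user, defaults) {
  for (k in names(defaults)) {
    if (is.null(user[[k]])) {
      user[[k]] <- defaults[[k]]
    } else if (is.list(defaults[[k]]) && is.list(user[[k]])) {
      user[[k]] <- utils::modifyList(defaults[[k]], user[[k]])
    }
  }
  user
}

load_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  merge_config(config, default_pipeline_config(config$seed %||% 1))
}

log_line <- function(log_path, stage, msg) {
  line <- sprintf("[%s] %s", stage, msg)
  cat(line, "\n", sep = "", file = log_path, append = TRUE)
  invisible(line)
}

#' Run the full texture-prediction workflow
#'
#' Generates (or receives) region spectra and texture tables, smooths the
#' spectra, optionally selects optimal wavelengths by the RC method per
#' (region, indicator), fits the configured model battery, evaluates every
#' model, retains the best per cell, and optionally renders prediction maps
#' from a synthetic cube. All outputs are written under `out_dir` together
#' with a structured log and a manifest of content hashes; identical
#' config + seed reproduces the report byte-for-byte.
#'
#' @param config Partial config list or YAML path; see
#'   [default_pipeline_config()]. To run on your own data pass
#'   `data = list(spectra = <named list of spectra_matrix>, texture = <table>)`
#'   inside the config instead of `simulate`.
#' @param out_dir Output directory (created if missing).
#' @return List with `report` (all evaluation rows), `retained` (best per
#'   cell), `paths` of written files, and `config` as resolved.
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("carptex_run_")) {
  cfg <- load_pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "log.txt")
  cat("", file = log_path) # truncate
  t0 <- Sys.time()
  log_line(log_path, "start", sprintf("seed=%d", cfg$seed))

  # --- data stage -----------------------------------------------------------
  if (!is.null(cfg$data)) {
    spectra_by_region <- cfg$data$spectra
    texture <- validate_texture_table(cfg$data$texture)
    gen <- NULL
    log_line(log_path, "data", sprintf("user data, %d region(s)",
                                       length(spectra_by_region)))
  } else {
    sim <- cfg$simulate
    gc_ <- generator_config(
      n_samples = sim$n_samples, n_bands = sim$n_bands,
      regions = sim$regions, n_latent = sim$n_latent,
      noise_sd_spectral = sim$noise_sd_spectral,
      noise_sd_texture = sim$noise_sd_texture,
      nonlinearity = sim$nonlinearity, two_cluster = isTRUE(sim$two_cluster),
      seed = derive_seed(cfg$seed, "simulate")
    )
    gen <- generate_dataset(gc_)
    spectra_by_region <- gen$spectra
    texture <- gen$texture
    log_line(log_path, "simulate",
             sprintf("n=%d bands=%d regions=%s", sim$n_samples, sim$n_bands,
                     paste(sim$regions, collapse = ",")))
  }

  # --- preprocessing stage --------------------------------------------------
  if (!is.null(cfg$sg)) {
    spectra_by_region <- purrr::map(
      spectra_by_region, sg_smooth,
      window = cfg$sg$window, polyorder = cfg$sg$polyorder
    )
    log_line(log_path, "preprocess",
             sprintf("sg window=%d polyorder=%d", cfg$sg$window,
                     cfg$sg$polyorder))
  }

  # --- selection + modelling + evaluation -----------------------------------
  reports <- list()
  subsets <- list()
  for (region in names(spectra_by_region)) {
    spec <- spectra_by_region[[region]]
    split <- list(fraction = cfg$split$fraction,
                  strategy = cfg$split$strategy %||% "random",
                  seed = derive_seed(cfg$seed, paste0("split_", region)))
    for (indicator in cfg$indicators) {
      subset <- NULL
      if (!is.null(cfg$selection) && identical(cfg$selection$method, "rc")) {
        # selection uses calibration samples only, to keep the prediction
        # set untouched by any model choice
        sp <- split_dataset(nrow(spec$X), fraction = split$fraction,
                            seed = split$seed, strategy = split$strategy,
                            X = spec$X)
        tex_r <- dplyr::filter(texture, .data$region == !!region)
        y_cal <- tex_r[[indicator]][match(spec$sample_ids[sp$calibration],
                                          tex_r$sample_id)]
        prof <- compute_rc_profile(
          spec$X[sp$calibration, , drop = FALSE], y_cal,
          cv_folds = cfg$model_opts$cv_folds %||% 5
        )
        subset <- select_by_rc(prof,
                               mode = cfg$selection$mode %||% "peak_threshold",
                               param = cfg$selection$param %||% 0.1)
        subsets[[paste(region, indicator, sep = ".")]] <- subset
        log_line(log_path, "select",
                 sprintf("%s/%s: %d wavelengths (%s)", region, indicator,
                         length(subset$indices), cfg$selection$mode %||%
                           "peak_threshold"))
      }
      opts <- cfg$model_opts
      opts$seed <- derive_seed(cfg$seed, paste0("bpann_", region, "_", indicator))
      rep <- evaluate_models(spec, texture, indicator,
                             models = cfg$models, subset = subset,
                             split = split, model_opts = opts)
      reports[[paste(region, indicator, sep = ".")]] <- rep
      log_line(log_path, "evaluate",
               sprintf("%s/%s: best r_p=%.4f (%s)", region, indicator,
                       max(rep$r_p), rep$model[which.max(rep$r_p)]))
    }
  }
  report <- dplyr::bind_rows(reports)
  retained <- rank_models(report)

  # --- outputs --------------------------------------------------------------
  fmt <- function(df) {
    df <- as.data.frame(df)
    num <- vapply(df, is.numeric, TRUE)
    df[num] <- lapply(df[num], function(v) formatC(v, format = "g", digits = 10))
    df
  }
  report_path <- file.path(out_dir, "report.csv")
  retained_path <- file.path(out_dir, "retained.csv")
  utils::write.csv(fmt(report), report_path, row.names = FALSE)
  utils::write.csv(fmt(retained), retained_path, row.names = FALSE)

  map_paths <- character(0)
  if (!is.null(cfg$visualize) && !is.null(gen)) {
    vz <- cfg$visualize
    cube_cfg <- generator_config(
      n_samples = 2, n_bands = cfg$simulate$n_bands,
      regions = names(spectra_by_region)[1],
      noise_sd_spectral = cfg$simulate$noise_sd_spectral,
      seed = derive_seed(cfg$seed, "cube")
    )
    cube <- generate_cube(cube_cfg, vz$rows %||% 48, vz$cols %||% 48)$cube
    region1 <- names(spectra_by_region)[1]
    spec1 <- spectra_by_region[[region1]]
    for (indicator in cfg$indicators) {
      best <- dplyr::filter(retained, .data$region == region1,
                            .data$indicator == !!indicator)
      tex_r <- dplyr::filter(texture, .data$region == region1)
      y <- tex_r[[indicator]][match(spec1$sample_ids, tex_r$sample_id)]
      model <- fit_plsr(spec1, y) # raw-unit model for mapping
      map <- predict_pixelwise(cube, model, indicator = indicator)
      p <- file.path(out_dir, sprintf("map_%s_%s.png", region1, indicator))
      render_map(map, p)
      map_paths <- c(map_paths, p)
      log_line(log_path, "visualize",
               sprintf("%s/%s via %s", region1, indicator, best$model[1]))
    }
  }

  paths <- c(report = report_path, retained = retained_path, map_paths)
  manifest <- list(
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("carptex")),
    files = lapply(stats::setNames(as.list(unname(paths)), basename(paths)),
                   function(p) unname(tools::md5sum(p)))
  )
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)
  log_line(log_path, "done",
           sprintf("%.1fs elapsed", as.numeric(Sys.time() - t0, units = "secs")))

  list(report = report, retained = retained, subsets = subsets,
       paths = c(paths, manifest = manifest_path, log = log_path),
       config = cfg)
}

#' Compare full-spectrum and RC-subset prediction accuracy
#'
#' For each (region, indicator) cell, evaluates PLSR (or the configured
#' models) on the full spectrum and on the RC-selected wavelength subset
#' with an identical split, and reports paired r_p values and their delta.
#'
#' @param config Partial pipeline config; `selection` defaults to the RC
#'   peak-threshold rule. `models` defaults to "plsr".
#' @param subset_override Optional `wavelength_subset` applied to every cell
#'   instead of RC selection (used for degenerate-comparison checks).
#' @return Tibble with one row per cell: r_p_full, r_p_subset, n_wl_subset,
#'   delta = r_p_subset - r_p_full; the mean absolute delta is attached as
#'   attribute `mean_abs_delta`.
#' @export
compare_full_vs_subset <- function(config = list(), subset_override = NULL) {
  cfg <- load_pipeline_config(config)
  if (is.null(cfg$selection)) {
    cfg$selection <- list(method = "rc", mode = "peak_threshold", param = 0.1)
  }
  if (identical(cfg$models, model_kinds())) cfg$models <- "plsr"
  sim <- cfg$simulate
  gc_ <- generator_config(
    n_samples = sim$n_samples, n_bands = sim$n_bands, regions = sim$regions,
    n_latent = sim$n_latent, noise_sd_spectral = sim$noise_sd_spectral,
    noise_sd_texture = sim$noise_sd_texture, nonlinearity = sim$nonlinearity,
    two_cluster = isTRUE(sim$two_cluster),
    seed = derive_seed(cfg$seed, "simulate")
  )
  gen <- generate_dataset(gc_)
  rows <- list()
  for (region in names(gen$spectra)) {
    spec <- sg_smooth(gen$spectra[[region]],
                      cfg$sg$window, cfg$sg$polyorder)
    split <- list(fraction = cfg$split$fraction,
                  strategy = cfg$split$strategy %||% "random",
                  seed = derive_seed(cfg$seed, paste0("split_", region)))
    sp <- split_dataset(nrow(spec$X), fraction = split$fraction,
                        seed = split$seed, strategy = split$strategy,
                        X = spec$X)
    tex_r <- dplyr::filter(gen$texture, .data$region == !!region)
    for (indicator in cfg$indicators) {
      full <- evaluate_models(spec, gen$texture, indicator,
                              models = cfg$models, split = sp,
                              model_opts = cfg$model_opts)
      subset <- subset_override
      if (is.null(subset)) {
        y_cal <- tex_r[[indicator]][match(spec$sample_ids[sp$calibration],
                                          tex_r$sample_id)]
        prof <- compute_rc_profile(spec$X[sp$calibration, , drop = FALSE],
                                   y_cal,
                                   cv_folds = cfg$model_opts$cv_folds %||% 5)
        subset <- select_by_rc(prof,
                               mode = cfg$selection$mode %||% "peak_threshold",
                               param = cfg$selection$param %||% 0.1)
      }
      sub <- evaluate_models(spec, gen$texture, indicator,
                             models = cfg$models, subset = subset,
                             split = sp, model_opts = cfg$model_opts)
      best_full <- rank_models(full)
      best_sub <- rank_models(sub)
      rows[[paste(region, indicator)]] <- tibble::tibble(
        region = region, indicator = indicator,
        r_p_full = best_full$r_p, r_p_subset = best_sub$r_p,
        n_wl_subset = length(subset$indices),
        delta = best_sub$r_p - best_full$r_p
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "mean_abs_delta") <- mean(abs(out$delta))
  out
}
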