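# Thin orchestration layer: dispatch a configured stage, write its
# outputs and a run manifest sufficient to re-run it.

#' Run a configured pipeline stage
#'
#' Dispatches one stage of the analysis (`simulate`, `sweep`, `fit`,
#' `pathstats`, `synth_growth`, `synth_paths` or `scenario`) from a YAML/
#' JSON file or an R list, writes its outputs as CSV/JSON into `out_dir`,
#' and records a manifest (`manifest.json`) with the command, the full
#' configuration snapshot, the seed, the package version, output paths
#' and timestamps. A single root seed drives every stage; deterministic
#' stages re-run bit-identically from the manifest.
#'
#' Config fields: `command` (required), `seed`, plus per-command options:
#' * `simulate` / `sweep`: any [sim_config()] field; `sweep` additionally
#'   takes `grid` (named list of vectors) and `n_replicates`.
#' * `fit`: `input` (growth-curve CSV: either `time_h,density_per_ml` or
#'   long format with a `replicate` column, which is averaged), `model`
#'   (`"logistic"`, `"cr"` or `"both"`), `r0`, `KN`.
#' * `pathstats`: `input` (paths CSV `id,frame,x,y`), `min_duration`,
#'   `fps`.
#' * `synth_growth`, `synth_paths`, `scenario`: generator arguments.
#'
#' @param config Path to a YAML/JSON config file, or a named list.
#' @param out_dir Output directory (created if missing).
#'
#' @return The manifest, invisibly, as a named list.
#' @export
run_pipeline <- function(config, out_dir = ".") {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("[.]json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config) || is.null(config$command)) {
    stop("config must name a command (one of simulate, sweep, fit, ",
         "pathstats, synth_growth, synth_paths, scenario)")
  }
  cmd <- config$command
  known <- c("simulate", "sweep", "fit", "pathstats", "synth_growth",
             "synth_paths", "scenario")
  if (!cmd %in% known) {
    stop("unknown command '", cmd, "'; expected one of: ",
         paste(known, collapse = ", "))
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  outputs <- switch(cmd,
    simulate = stage_simulate(config, out_dir, seed),
    sweep = stage_sweep(config, out_dir, seed),
    fit = stage_fit(config, out_dir),
    pathstats = stage_pathstats(config, out_dir),
    synth_growth = stage_synth_growth(config, out_dir, seed),
    synth_paths = stage_synth_paths(config, out_dir, seed),
    scenario = stage_scenario(config, out_dir, seed)
  )
  manifest <- list(
    command = cmd,
    config = config,
    seed = seed,
    package_version = as.character(packageVersion("rangexp")),
    outputs = outputs,
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

cfg_fields <- function(config, fields) {
  config[intersect(names(config), fields)]
}

sim_fields <- c("n_patches", "n_core", "burn_in", "max_gen", "K", "lambda0",
                "mu", "d_max", "a_max", "invb_max", "e", "p_mut", "mut_sd",
                "four_way", "e_max", "tradeoff_exponent", "inflow",
                "refuge", "n_init_per_patch", "N_init", "record_every")

stage_simulate <- function(config, out_dir, seed) {
  cfg <- do.call(sim_config, cfg_fields(config, sim_fields))
  run <- run_simulation(cfg, seed = seed)
  records_path <- file.path(out_dir, "records.csv")
  profile_path <- file.path(out_dir, "profile.csv")
  write.csv(run$records, records_path, row.names = FALSE)
  write.csv(run$profile, profile_path, row.names = FALSE)
  message("simulate: ", run$generations, " generations, front at patch ",
          tail(run$front, 1))
  c(records = records_path, profile = profile_path)
}

stage_sweep <- function(config, out_dir, seed) {
  base <- do.call(sim_config, cfg_fields(config, sim_fields))
  n_rep <- if (is.null(config$n_replicates)) 20 else config$n_replicates
  sw <- sweep_simulations(grid = if (is.null(config$grid)) list() else config$grid,
                          n_replicates = n_rep, seed = seed,
                          base_config = base)
  runs_path <- file.path(out_dir, "sweep_runs.csv")
  prof_path <- file.path(out_dir, "sweep_profiles.csv")
  out_path <- file.path(out_dir, "sweep_outcomes.csv")
  write.csv(sw$runs, runs_path, row.names = FALSE)
  write.csv(sw$profiles, prof_path, row.names = FALSE)
  write.csv(sw$outcomes, out_path, row.names = FALSE)
  c(runs = runs_path, profiles = prof_path, outcomes = out_path)
}

read_curve_input <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  if ("replicate" %in% names(d)) pool_replicates(d) else {
    growth_series(d$time_h, d$density_per_ml)
  }
}

stage_fit <- function(config, out_dir) {
  if (is.null(config$input)) stop("fit requires an 'input' CSV path")
  series <- read_curve_input(config$input)
  model <- if (is.null(config$model)) "both" else config$model
  r0 <- if (is.null(config$r0)) 0.24 else config$r0
  KN <- if (is.null(config$KN)) 3.6e7 else config$KN
  fits <- list()
  if (model %in% c("logistic", "both")) {
    fits$logistic <- fit_logistic(series)
  }
  if (model %in% c("cr", "consumer_resource", "both")) {
    fits$consumer_resource <- fit_consumer_resource(series, fixed_r0 = r0,
                                                    fixed_KN = KN)
  }
  report <- lapply(fits, function(f) {
    list(params = as.list(f$params), fixed = as.list(f$fixed),
         rss = f$rss, n_obs = f$n_obs, k_free = f$k_free, aic = f$aic)
  })
  if (length(fits) == 2) {
    cmpr <- compare_models(fits$logistic, fits$consumer_resource)
    report$comparison <- list(delta_aic = cmpr$delta_aic,
                              preferred = cmpr$preferred)
  }
  fit_path <- file.path(out_dir, "fits.json")
  jsonlite::write_json(report, fit_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  tt <- seq(min(series$time_h), max(series$time_h), length.out = 200)
  pred <- data.frame(time_h = tt)
  for (nm in names(fits)) pred[[nm]] <- predict(fits[[nm]], tt)
  pred_path <- file.path(out_dir, "predicted_curves.csv")
  write.csv(pred, pred_path, row.names = FALSE)
  c(fits = fit_path, predicted = pred_path)
}

stage_pathstats <- function(config, out_dir) {
  if (is.null(config$input)) stop("pathstats requires an 'input' CSV path")
  fps <- if (is.null(config$fps)) 25 else config$fps
  min_dur <- if (is.null(config$min_duration)) 4 else config$min_duration
  paths <- read_paths(config$input, fps = fps)
  stats <- path_stats(paths, min_duration = min_dur, fps = fps)
  stats_path <- file.path(out_dir, "path_stats.csv")
  pop_path <- file.path(out_dir, "population_movement.csv")
  write.csv(stats, stats_path, row.names = FALSE)
  write.csv(population_movement(stats), pop_path, row.names = FALSE)
  c(path_stats = stats_path, population = pop_path)
}

stage_synth_growth <- function(config, out_dir, seed) {
  truth <- if (!is.null(config$logistic)) {
    do.call(logistic_params, config$logistic)
  } else if (!is.null(config$cr)) {
    do.call(cr_params, config$cr)
  } else {
    core_margin_truths()$core
  }
  design <- if (is.null(config$design)) sampling_design() else {
    do.call(sampling_design, config$design)
  }
  n_rep <- if (is.null(config$n_replicates)) 6 else config$n_replicates
  curves <- generate_growth_curves(truth, design, n_rep, seed = seed)
  p <- file.path(out_dir, "growth_curves.csv")
  write.csv(curves, p, row.names = FALSE)
  c(curves = p)
}

stage_synth_paths <- function(config, out_dir, seed) {
  speed <- if (is.null(config$speed)) 50 else config$speed
  circ_sd <- if (is.null(config$circ_sd)) 1 else config$circ_sd
  n_paths <- if (is.null(config$n_paths)) 100 else config$n_paths
  paths <- generate_crw_paths(speed, circ_sd, n_paths, seed = seed)
  p <- file.path(out_dir, "paths.csv")
  write_paths(paths, p)
  c(paths = p)
}

stage_scenario <- function(config, out_dir, seed) {
  n_rep <- if (is.null(config$n_replicates)) 6 else config$n_replicates
  sc <- generate_core_margin_scenario(seed, n_replicates = n_rep)
  curves_path <- file.path(out_dir, "scenario_curves.csv")
  write.csv(sc$curves, curves_path, row.names = FALSE)
  outs <- c(curves = curves_path)
  for (tr in names(sc$paths)) {
    p <- file.path(out_dir, paste0("scenario_paths_", tr, ".csv"))
    write_paths(sc$paths[[tr]], p)
    outs[[paste0("paths_", tr)]] <- p
  }
  outs
}
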