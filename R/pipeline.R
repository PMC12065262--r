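#' Default configuration for the end-to-end toy run
#'
#' A desk-scale replica of the full workflow: a coarse (4-degree) North
#' Pacific grid, two tagged fish with 60-day deployments, three emulated
#' climate-model sources, and a small posterior ensemble. Every stage's
#' randomness derives from the single root seed via named substreams.
#'
#' @param seed root seed
#' @param out_dir output directory
#' @return nested configuration list understood by [run_all()]
#' @export
default_run_config <- function(seed = 42L,
                               out_dir = file.path(tempdir(),
                                                   "energyscape_run")) {
  list(seed = as.integer(seed), out_dir = out_dir,
       synth = list(n_fish = 2L, deployment_days = 60L,
                    lat_range = c(20, 52), lon_range = c(150, -130),
                    resolution = 4, warming_offset = 2),
       sources = c("esm1", "esm2", "esm3"),
       ensemble = list(k = 2L, percentiles = c(5, 95), month = 7L),
       constants = list())
}

#' Read / write a run configuration as YAML
#' @param path YAML file path
#' @param config configuration list
#' @return `read_run_config()`: a configuration list merged over the
#'   defaults; `write_run_config()`: `path`, invisibly
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  config <- default_run_config()
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(config[[nm]]))
      config[[nm]][names(user[[nm]])] <- user[[nm]]
    else config[[nm]] <- user[[nm]]
  }
  config
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes the workflow end to end at the configured scale: synthetic
#' inputs (fields, tags, laboratory tables), daily-HIF extraction, model
#' fitting, track energetics, seascape projection with habitat-change
#' summaries across the source ensemble, and posterior-uncertainty
#' propagation. Each stage writes plain-text outputs under
#' `config$out_dir`; a `manifest.json` records the seed and the content
#' hash of every output file. Stages whose outputs already exist are
#' skipped unless `force = TRUE` or an upstream stage was rerun, so
#' deleting one intermediate regenerates only it and its downstream
#' stages.
#'
#' @param config configuration list from [default_run_config()] or
#'   [read_run_config()]
#' @param force rerun all stages regardless of existing outputs
#' @return invisibly, a list with the manifest and key in-memory artifacts
#' @export
run_all <- function(config = default_run_config(), force = FALSE) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  cfg <- do.call(synth_config,
                 c(list(seed = config$seed), config$synth))
  const <- do.call(energetics_constants, config$constants)
  fish_ids <- sprintf("fish%02d", seq_len(cfg$n_fish))
  pth <- function(...) file.path(out, paste0(...))

  stage_outputs <- list(
    synth = c(pth("env_obs_historical.csv"),
              as.vector(outer(config$sources, c("historical", "future"),
                              function(s, p) pth("env_", s, "_", p, ".csv"))),
              as.vector(outer(fish_ids, c("_daily.csv", "_minute.csv"),
                              function(f, s) pth(f, s))),
              pth("respirometry.csv"), pth("feeding_trials.csv"),
              pth("config.yaml")),
    hif = pth("hif_", fish_ids, ".csv"),
    fit = pth("model_", c("depth_day", "depth_night", "cost", "hif",
                          "ingestion"), ".json"),
    track = pth("track_", fish_ids, ".csv"),
    project = c(pth("habitat_change.csv"), pth("ensemble_summary.csv")),
    uncertainty = c(pth("anomaly_percentiles.csv"),
                    pth("variance_attribution.csv")))

  run_stage <- logical(length(stage_outputs))
  names(run_stage) <- names(stage_outputs)
  upstream <- FALSE
  for (s in names(stage_outputs)) {
    run_stage[s] <- force || upstream || !all(file.exists(stage_outputs[[s]]))
    upstream <- upstream || run_stage[s]
  }

  ## stage: synth -------------------------------------------------------
  env_obs <- generate_env_fields(cfg, "historical", "obs")
  envs_hist <- lapply(stats::setNames(nm = config$sources),
                      function(s) generate_env_fields(cfg, "historical", s))
  envs_fut <- lapply(stats::setNames(nm = config$sources),
                     function(s) generate_env_fields(cfg, "future", s))
  tags <- generate_tag_records(cfg, env = env_obs)
  resp <- generate_respirometry(cfg)
  trials <- generate_feeding_trials(cfg)
  if (run_stage["synth"]) {
    message("stage synth: writing inputs to ", out)
    write_env_fields(env_obs, pth("env_obs_historical.csv"))
    for (s in config$sources) {
      write_env_fields(envs_hist[[s]], pth("env_", s, "_historical.csv"))
      write_env_fields(envs_fut[[s]], pth("env_", s, "_future.csv"))
    }
    for (f in fish_ids) write_tag_record(tags[[f]], pth(f))
    utils::write.csv(resp, pth("respirometry.csv"), row.names = FALSE)
    utils::write.csv(trials, pth("feeding_trials.csv"), row.names = FALSE)
    # the written copy omits the output path so that runs of the same
    # seed/config are content-identical wherever they land
    config_portable <- config
    config_portable$out_dir <- NULL
    write_run_config(config_portable, pth("config.yaml"))
  }

  ## stage: hif ---------------------------------------------------------
  daily_hif <- lapply(tags, function(tag)
    compute_daily_hif(tag, estimate_baseline(tag)))
  if (run_stage["hif"]) {
    message("stage hif: extracting daily heat increment of feeding")
    for (f in fish_ids)
      utils::write.csv(daily_hif[[f]], pth("hif_", f, ".csv"),
                       row.names = FALSE)
  }

  ## stage: fit ---------------------------------------------------------
  models <- fit_energetics_models(tags, env_obs, resp, trials,
                                  daily_hif = daily_hif)
  if (run_stage["fit"]) {
    message("stage fit: fitting the model chain")
    for (nm in names(models))
      write_smooth_model(models[[nm]], pth("model_", nm, ".json"))
  }

  ## stage: track -------------------------------------------------------
  if (run_stage["track"]) {
    message("stage track: daily track energetics")
    for (f in fish_ids) {
      tr <- track_daily_energetics(tags[[f]], models, const,
                                   daily_hif = daily_hif[[f]])
      utils::write.csv(tr, pth("track_", f, ".csv"), row.names = FALSE)
    }
  }

  ## stage: project -----------------------------------------------------
  summaries <- NULL
  if (run_stage["project"]) {
    message("stage project: seascape maps and habitat change")
    summaries <- do.call(rbind, lapply(config$sources, function(s)
      habitat_change(project_energetics(envs_hist[[s]], models, const),
                     project_energetics(envs_fut[[s]], models, const),
                     const)))
    utils::write.csv(summaries, pth("habitat_change.csv"),
                     row.names = FALSE)
    utils::write.csv(ensemble_summary(summaries),
                     pth("ensemble_summary.csv"), row.names = FALSE)
  }

  ## stage: uncertainty -------------------------------------------------
  if (run_stage["uncertainty"]) {
    message("stage uncertainty: posterior propagation")
    k <- config$ensemble$k
    ens <- build_ensemble(models, k = k,
                          seed = derive_seed(config$seed, "ensemble"),
                          percentiles = config$ensemble$percentiles)
    members <- ensemble_realizations(ens)
    n_eval <- min(nrow(members), 16L)
    sel <- members[round(seq(1, nrow(members), length.out = n_eval)), ,
                   drop = FALSE]
    dmat <- ensemble_delta_balance(ens, envs_hist[[1]], envs_fut[[1]],
                                   const, month = config$ensemble$month,
                                   members = sel)
    ap <- anomaly_percentiles(dmat, config$ensemble$percentiles)
    g <- envs_hist[[1]]$grid
    pc <- expand.grid(lon = envs_hist[[1]]$lon, lat = envs_hist[[1]]$lat,
                      KEEP.OUT.ATTRS = FALSE)
    for (i in seq_along(config$ensemble$percentiles))
      pc[[rownames(ap$percentiles)[i]]] <- ap$percentiles[i, ]
    pc$overlap_zero <- ap$overlap_zero
    utils::write.csv(pc, pth("anomaly_percentiles.csv"), row.names = FALSE)
    va <- variance_attribution(models, envs_hist, envs_fut, const,
                               k = min(k, 5),
                               seed = derive_seed(config$seed, "va"),
                               month = config$ensemble$month)
    va_tab <- va$table
    va_tab$total_variance <- va$total_variance
    va_tab$interaction_remainder <- va$interaction_remainder
    utils::write.csv(va_tab, pth("variance_attribution.csv"),
                     row.names = FALSE)
  }

  ## manifest -----------------------------------------------------------
  files <- sort(unname(unlist(stage_outputs)))
  files <- c(files, vapply(files[grepl("^env_.*\\.csv$", basename(files))],
                           function(f) paste0(f, ".meta.json"), ""))
  files <- files[file.exists(files)]
  manifest <- list(seed = config$seed,
                   stages_run = names(run_stage)[run_stage],
                   files = lapply(stats::setNames(files, basename(files)),
                                  function(f)
                                    unname(tools::md5sum(f))))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(manifest = manifest, models = models,
                 summaries = summaries, config = config))
}
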