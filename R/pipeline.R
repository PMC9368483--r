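## Pipeline orchestration: config file, stages, manifest -----------------------

.cohortKeys <- c("n_per_group", "n_veins_per_eye", "n_arteries_per_eye",
                 "frame_rate_hz", "modulation_frequency_hz",
                 "pooled_corr_o2a_vv", "pooled_corr_o2a_nfl", "o2av_sd",
                 "vessel_cv", "region_cv", "phase_noise_sd_rad",
                 "track_noise_sd_um", "profile_noise_frac",
                 "profile_blur_sd_um", "pixel_pitch_um",
                 "n_spheres_per_vein", "n_frames_per_track",
                 "trace_samples")
.oximetryKeys <- c("tau0_s", "kq_per_mmhg_s", "p50_mmhg", "hill_n",
                   "hb_g_per_dl", "hb_capacity_ml_per_g",
                   "solubility_ml_per_dl_per_mmhg")

#' Assemble an in-memory pipeline configuration
#'
#' @param cohort a [CohortConfig-class].
#' @param constants an [OximetryConstants-class].
#' @param alpha significance level in (0, 1).
#' @param n_per_group animals per group (`NULL` = calibrated group sizes).
#' @return list with class `retinox_pipeline_config`.
#' @export
pipelineConfig <- function(cohort = cohortConfig(),
                           constants = oximetryConstants(),
                           alpha = 0.05,
                           n_per_group = NULL) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)")
  validObject(cohort); validObject(constants)
  structure(list(cohort = cohort, constants = constants, alpha = alpha,
                 n_per_group = n_per_group),
            class = "retinox_pipeline_config")
}

#' Read and validate a pipeline configuration file
#'
#' Strict YAML parsing: unknown keys are an error, every numeric key carries
#' its unit as a suffix (e.g. `tau0_s`, `pixel_pitch_um`), and all class
#' invariants are checked on construction, so an invalid value fails with a
#' message naming the offending key.
#'
#' @param path YAML file path.
#' @param seed optional integer overriding the file's seed.
#' @return a `retinox_pipeline_config` list (see [pipelineConfig()]).
#' @export
validateConfig <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  known_top <- c("seed", "alpha", "cohort", "oximetry")
  unknown <- setdiff(names(y), known_top)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (blk in list(c("cohort", list(.cohortKeys)),
                   c("oximetry", list(.oximetryKeys)))) {
    nm <- blk[[1L]]
    if (!is.null(y[[nm]])) {
      bad <- setdiff(names(y[[nm]]), blk[[2L]])
      if (length(bad))
        stop("unknown key(s) in '", nm, "' block: ",
             paste(bad, collapse = ", "))
    }
  }
  seed <- if (!is.null(seed)) as.integer(seed)
          else as.integer(y$seed %||% 1L)
  alpha <- y$alpha %||% 0.05

  co <- y$cohort %||% list()
  cohort <- tryCatch(
    cohortConfig(
      n_veins_per_eye = co$n_veins_per_eye %||% 4L,
      n_arteries_per_eye = co$n_arteries_per_eye %||% 4L,
      frame_rate_hz = co$frame_rate_hz %||% 104,
      modulation_frequency_hz = co$modulation_frequency_hz %||% 1000,
      pooled_corr_o2a_vv = co$pooled_corr_o2a_vv %||% -0.57,
      pooled_corr_o2a_nfl = co$pooled_corr_o2a_nfl %||% -0.53,
      o2av_sd = co$o2av_sd %||% 1.3,
      vessel_cv = co$vessel_cv %||% 0.10,
      region_cv = co$region_cv %||% 0.05,
      phase_noise_sd_rad = co$phase_noise_sd_rad %||% 0.01,
      track_noise_sd_um = co$track_noise_sd_um %||% 1,
      profile_noise_frac = co$profile_noise_frac %||% 0.01,
      profile_blur_sd_um = co$profile_blur_sd_um %||% 2,
      pixel_pitch_um = co$pixel_pitch_um %||% 1,
      n_spheres_per_vein = co$n_spheres_per_vein %||% 8L,
      n_frames_per_track = co$n_frames_per_track %||% 12L,
      trace_samples = co$trace_samples %||% 192L,
      seed = seed),
    error = function(e) stop("invalid 'cohort' block: ", conditionMessage(e),
                             call. = FALSE))
  ox <- y$oximetry %||% list()
  constants <- tryCatch(
    oximetryConstants(
      tau0_s = ox$tau0_s %||% 637e-6,
      kq_per_mmhg_s = ox$kq_per_mmhg_s %||% 381,
      p50_mmhg = ox$p50_mmhg %||% 40,
      hill_n = ox$hill_n %||% 2.59,
      hb_g_per_dl = ox$hb_g_per_dl %||% 15,
      hb_capacity_ml_per_g = ox$hb_capacity_ml_per_g %||% 1.39,
      solubility_ml_per_dl_per_mmhg = ox$solubility_ml_per_dl_per_mmhg %||%
        0.003),
    error = function(e) stop("invalid 'oximetry' block: ",
                             conditionMessage(e), call. = FALSE))
  pipelineConfig(cohort, constants, alpha,
                 n_per_group = co$n_per_group)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.writeCsv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  path
}

.cohortSignalTables <- function(cohort) {
  animals <- cohort@animals
  traces <- do.call(rbind, lapply(animals, function(a)
    do.call(rbind, lapply(a@traces, function(tr)
      data.frame(animal_id = a@animalId, vessel_id = tr@vesselId,
                 time_s = tr@timeS, signal = tr@signal)))))
  tracks <- do.call(rbind, lapply(animals, function(a)
    do.call(rbind, lapply(unlist(a@tracks), function(tk)
      data.frame(animal_id = a@animalId, vein_id = tk@veinId,
                 track_id = tk@trackId, frame_index = tk@frameIndex,
                 x_um = tk@xUm, y_um = tk@yUm)))))
  profiles <- do.call(rbind, lapply(animals, function(a)
    do.call(rbind, lapply(a@profiles, function(pr)
      data.frame(animal_id = a@animalId, vessel_id = pr@vesselId,
                 position_um = pr@positionUm, intensity = pr@intensity)))))
  boundaries <- do.call(rbind, lapply(animals, function(a)
    rbind(data.frame(animal_id = a@animalId, region = "nasal",
                     boundary_index = seq_along(a@boundariesNasal),
                     depth_um = a@boundariesNasal),
          data.frame(animal_id = a@animalId, region = "temporal",
                     boundary_index = seq_along(a@boundariesTemporal),
                     depth_um = a@boundariesTemporal))))
  list(traces = traces, tracks = tracks, profiles = profiles,
       boundaries = boundaries)
}

.configAsList <- function(config) {
  co <- config$cohort; ox <- config$constants
  list(
    seed = co@seed, alpha = config$alpha,
    n_per_group = config$n_per_group,
    cohort = list(
      n_veins_per_eye = co@nVeinsPerEye,
      n_arteries_per_eye = co@nArteriesPerEye,
      frame_rate_hz = co@frameRateHz,
      modulation_frequency_hz = co@modulationFrequencyHz,
      pooled_corr_o2a_vv = co@pooledCorrO2aVv,
      pooled_corr_o2a_nfl = co@pooledCorrO2aNfl,
      o2av_sd = co@o2avSd,
      vessel_cv = co@vesselCv, region_cv = co@regionCv,
      phase_noise_sd_rad = co@phaseNoiseSdRad,
      track_noise_sd_um = co@trackNoiseSdUm,
      profile_noise_frac = co@profileNoiseFrac,
      profile_blur_sd_um = co@profileBlurSdUm,
      pixel_pitch_um = co@pixelPitchUm,
      n_spheres_per_vein = co@nSpheresPerVein,
      n_frames_per_track = co@nFramesPerTrack,
      trace_samples = co@traceSamples),
    oximetry = list(
      tau0_s = ox@tau0S, kq_per_mmhg_s = ox@kqPerMmHgS,
      p50_mmhg = ox@p50MmHg, hill_n = ox@hillN,
      hb_g_per_dl = ox@hbGPerDl,
      hb_capacity_ml_per_g = ox@hbCapacityMlPerG,
      solubility_ml_per_dl_per_mmhg = ox@solubilityMlPerDlPerMmHg),
    calibrations = lapply(config$cohort@calibrations, function(g)
      list(group = g@group, n_animals = g@nAnimals,
           means = as.list(g@means), sds = as.list(g@sds))))
}

#' Run the full pipeline: generate, measure, aggregate, report
#'
#' Executes all stages against a writable output directory and records a run
#' manifest. Outputs: the truth-level cohort table and raw-signal CSVs with a
#' JSON config sidecar (generate stage), the per-vessel measured table
#' (measure), the per-animal metrics table (metrics), the layer-thickness
#' table (morphometry), `report.json`/`report.txt` (stats), and
#' `manifest.json` with the seed, a config hash and per-file checksums.
#' Re-running with the same config and seed reproduces byte-identical CSVs.
#' A failing stage aborts with a stage-tagged error and removes the partial
#' outputs of this run.
#'
#' @param config a `retinox_pipeline_config` from [pipelineConfig()] or
#'   [validateConfig()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest as a list.
#' @export
runPipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "retinox_pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (file.access(out_dir, 2L) != 0L)
    stop("output directory is not writable: ", out_dir)
  written <- character()
  note <- function(p) { written <<- c(written, p); p }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(written)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  fp <- function(f) file.path(out_dir, f)

  cohort <- stage("generate", {
    ch <- generateCohort(config$cohort, n_per_group = config$n_per_group,
                         constants = config$constants)
    note(.writeCsv(ch@truthTable, fp("cohort_truth.csv")))
    sig <- .cohortSignalTables(ch)
    note(.writeCsv(sig$traces, fp("signals_traces.csv")))
    note(.writeCsv(sig$tracks, fp("signals_tracks.csv")))
    note(.writeCsv(sig$profiles, fp("signals_profiles.csv")))
    note(.writeCsv(sig$boundaries, fp("signals_boundaries.csv")))
    jsonlite::write_json(.configAsList(config), note(fp("config.json")),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    ch
  })
  se <- stage("measure", {
    s <- measureCohort(cohort, config$constants)
    note(.writeCsv(vesselTable(s), fp("vessels_measured.csv")))
    s
  })
  tab <- stage("metrics", {
    t <- animalTable(se)
    note(.writeCsv(t, fp("animal_metrics.csv")))
    t
  })
  stage("morphometry", {
    cols <- c("animal_id", "group", "nfl_rgcl", "ipl", "inl", "opl",
              "onl", "prl", "irl", "trt_hist", "trt_oct")
    note(.writeCsv(tab[, cols], fp("thickness.csv")))
  })
  report <- stage("stats", {
    r <- buildReport(tab, alpha = config$alpha)
    writeReport(r, note(fp("report.json")), note(fp("report.txt")))
    r
  })
  manifest <- stage("manifest", {
    files <- sort(basename(written))
    sums <- tools::md5sum(file.path(out_dir, files))
    m <- list(
      package = "retinox",
      version = as.character(utils::packageVersion("retinox")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      seed = config$cohort@seed,
      config_md5 = unname(tools::md5sum(fp("config.json"))),
      stages = c("generate", "measure", "metrics", "morphometry", "stats",
                 "manifest"),
      outputs = data.frame(file = files, md5 = unname(sums)))
    jsonlite::write_json(m, fp("manifest.json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "rows", pretty = TRUE)
    m
  })
  invisible(manifest)
}

## CSV readers for externally supplied raw signals -----------------------------

#' Read microsphere tracks from a long-format CSV
#'
#' Expects columns `track_id`, `frame_index`, `x_um`, `y_um` and either a
#' `vein_id` column or a single vein. Returns tracks grouped by vein.
#'
#' @param path CSV path.
#' @param frame_rate_hz acquisition rate of the recording (Hz).
#' @return named list (by vein) of lists of [MicrosphereTrack-class].
#' @export
readTracksCSV <- function(path, frame_rate_hz = 104) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("track_id", "frame_index", "x_um", "y_um")
  if (!all(need %in% names(df)))
    stop("tracks CSV must contain columns: ", paste(need, collapse = ", "))
  if (!"vein_id" %in% names(df)) df$vein_id <- "vein"
  lapply(split(df, df$vein_id), function(dv)
    lapply(split(dv, dv$track_id), function(dt) {
      dt <- dt[order(dt$frame_index), ]
      new("MicrosphereTrack", trackId = as.character(dt$track_id[1L]),
          veinId = as.character(dt$vein_id[1L]),
          frameIndex = as.integer(dt$frame_index),
          xUm = dt$x_um, yUm = dt$y_um, frameRateHz = frame_rate_hz)
    }))
}

#' Read caliber profiles from a long-format CSV
#'
#' Expects columns `vessel_id`, `position_um`, `intensity`.
#'
#' @param path CSV path.
#' @return named list of [CaliberProfile-class].
#' @export
readProfilesCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vessel_id", "position_um", "intensity")
  if (!all(need %in% names(df)))
    stop("profiles CSV must contain columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$vessel_id), function(dv) {
    dv <- dv[order(dv$position_um), ]
    new("CaliberProfile", vesselId = as.character(dv$vessel_id[1L]),
        positionUm = dv$position_um, intensity = dv$intensity)
  })
}

#' Read phosphorescence traces from a long-format CSV
#'
#' Expects columns `vessel_id`, `time_s`, `signal`.
#'
#' @param path CSV path.
#' @param modulation_frequency_hz excitation modulation frequency (Hz).
#' @return named list of [PhosphorescenceTrace-class].
#' @export
readTracesCSV <- function(path, modulation_frequency_hz = 1000) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("vessel_id", "time_s", "signal")
  if (!all(need %in% names(df)))
    stop("traces CSV must contain columns: ", paste(need, collapse = ", "))
  lapply(split(df, df$vessel_id), function(dv) {
    dv <- dv[order(dv$time_s), ]
    new("PhosphorescenceTrace", vesselId = as.character(dv$vessel_id[1L]),
        modulationFrequencyHz = modulation_frequency_hz,
        timeS = dv$time_s, signal = dv$signal, phaseRad = NA_real_)
  })
}
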