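# Pipeline orchestration: simulate -> preprocess -> window -> extract ->
# select -> train -> evaluate, as one configured, seeded, logged run.

#' Pipeline configuration
#'
#' Bundles every stage's settings. All randomness flows from `seed` via
#' named per-stage child streams, so a config fully determines the run's
#' outputs.
#'
#' @param sim [sim_config()] for the synthetic-data stage.
#' @param postures [posture_models()] table.
#' @param window [window_spec()].
#' @param cutoff_hz Low-pass cutoff for denoising, Hz.
#' @param selection `"pso"` (CFS + binary PSO on the full bank),
#'   `"preset"` (the published 27-feature subset), or `"none"` (all 84).
#' @param bins Discretization bins for the correlation table.
#' @param pso [pso_params()] used when `selection = "pso"`.
#' @param sensors Sensors whose features enter the bank (ablation).
#' @param roster [classifier_roster()].
#' @param eval_mode `"kfold"` or `"holdout"`.
#' @param k Folds for `"kfold"`.
#' @param train_fraction Training fraction for `"holdout"`.
#' @param seed Root seed.
#'
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = sim_config(),
                            postures = posture_models(),
                            window = window_spec(),
                            cutoff_hz = 5,
                            selection = c("pso", "preset", "none"),
                            bins = 10,
                            pso = pso_params(),
                            sensors = c("accelerometer", "gyroscope", "magnetometer"),
                            roster = classifier_roster(),
                            eval_mode = c("kfold", "holdout"),
                            k = 10, train_fraction = 0.75, seed = 1) {
  selection <- match.arg(selection)
  eval_mode <- match.arg(eval_mode)
  sensors <- match.arg(sensors, several.ok = TRUE)
  structure(
    list(
      sim = sim, postures = postures, window = window, cutoff_hz = cutoff_hz,
      selection = selection, bins = bins, pso = pso, sensors = sensors,
      roster = roster, eval_mode = eval_mode, k = k,
      train_fraction = train_fraction, seed = seed
    ),
    class = "pipeline_config"
  )
}

#' Restrict a feature matrix to a sensor subset
#'
#' Keeps only features computed from the chosen sensors (magnitude
#' features follow their sensor); selection should then be re-run on the
#' reduced bank. The full bank has 84 features; accelerometer + gyroscope
#' leaves 56 (6 channels x 9 statistics + 2 magnitudes), one sensor 28.
#'
#' @param fm Feature matrix tibble.
#' @param sensors Non-empty subset of
#'   `c("accelerometer", "gyroscope", "magnetometer")`.
#' @return The feature matrix with only the surviving feature columns.
#' @export
ablate_sensors <- function(fm, sensors) {
  sensors <- match.arg(
    sensors, c("accelerometer", "gyroscope", "magnetometer"),
    several.ok = TRUE
  )
  reg <- feature_registry(sensors = sensors)
  keep <- intersect(reg$name, feature_columns(fm))
  if (length(keep) == 0) {
    abort("no features left after ablation", class = "sitsense_empty_subset")
  }
  meta <- intersect(c("window_id", "label", "subject", "start"), names(fm))
  fm[c(meta, keep)]
}

#' Run the full pipeline
#'
#' Simulates the multi-subject dataset, preprocesses and windows it,
#' extracts the feature bank, selects features, evaluates every roster
#' classifier, and writes all artifacts plus a manifest into `out_dir`:
#' `raw.csv`, `features.csv`, `selection.json`, per-classifier
#' `eval_<id>.json/.txt/.csv`, and `manifest.json`. Re-running with the
#' same config reproduces all non-timing outputs byte-identically.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing); `NULL` skips all
#'   file output.
#' @param quiet Suppress progress messages.
#'
#' @return Invisibly, a list with `features`, `selection`, `reports`
#'   (named list of `posture_eval`), and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  timings <- list()
  say <- function(...) if (!quiet) message(...)
  tick <- function(stage, start) {
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), start, units = "secs"))
  }

  s <- Sys.time()
  say("simulating ", config$sim$subject_count, " subjects")
  config$sim$seed <- stage_seed(config$seed, "simulate")
  raw <- simulate_dataset(config$sim, config$postures)
  tick("simulate", s)

  s <- Sys.time()
  say("preprocessing and windowing")
  pre <- preprocess_recording(raw, cutoff_hz = config$cutoff_hz)
  windows <- make_windows(pre, config$window)
  tick("preprocess", s)

  s <- Sys.time()
  say("extracting features from ", nrow(windows), " windows")
  registry <- feature_registry(sensors = config$sensors)
  fm <- extract_features(windows, registry)
  fm <- left_join(fm, windows[c("window_id", "subject")], by = "window_id")
  tick("extract", s)

  s <- Sys.time()
  selection <- NULL
  features <- registry$name
  if (config$selection == "preset") {
    features <- intersect(published_feature_subset(), registry$name)
    say("using the published 27-feature preset (", length(features), " in bank)")
  } else if (config$selection == "pso") {
    say("CFS + binary PSO selection over ", length(features), " features")
    tab <- build_correlation_table(
      fm[c("label", registry$name)],
      bins = config$bins
    )
    psop <- config$pso
    psop$seed <- stage_seed(config$seed, "select")
    selection <- pso_search(tab, psop)
    features <- selection$names
    say("selected ", length(features), " features, merit ",
      format(selection$merit, digits = 4))
  }
  tick("select", s)

  s <- Sys.time()
  reports <- list()
  for (spec in config$roster) {
    say("evaluating ", spec$id)
    reports[[spec$id]] <- if (config$eval_mode == "kfold") {
      kfold_cv(fm, spec,
        k = config$k, features = features,
        seed = stage_seed(config$seed, paste0("eval-", spec$id))
      )
    } else {
      holdout_eval(fm, spec,
        features = features, train_fraction = config$train_fraction,
        seed = stage_seed(config$seed, paste0("eval-", spec$id))
      )
    }
  }
  tick("evaluate", s)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_imu_csv(raw, file.path(out_dir, "raw.csv"))
    write_feature_csv(
      fm[c("window_id", "label", registry$name)],
      file.path(out_dir, "features.csv")
    )
    if (!is.null(selection)) {
      write_selection_json(selection, file.path(out_dir, "selection.json"))
    }
    for (id in names(reports)) {
      write_eval_report(
        reports[[id]],
        file.path(out_dir, paste0("eval_", id, ".json")),
        file.path(out_dir, paste0("eval_", id, ".txt")),
        file.path(out_dir, paste0("eval_", id, ".csv"))
      )
    }
    manifest <- list(
      package_version = as.character(utils::packageVersion("sitsense")),
      seed = config$seed,
      sample_rate_hz = config$sim$sample_rate_hz,
      durations_s = as.list(config$sim$durations_s),
      subject_count = config$sim$subject_count,
      window = config$window[c("omega_t", "sample_rate_hz", "n_samples", "stride")],
      cutoff_hz = config$cutoff_hz,
      normalization = "per-channel per-subject max-abs",
      selection = config$selection,
      bins = config$bins,
      pso = config$pso[c("swarm_size", "iterations", "w", "c1", "c2", "v_max")],
      sensors = config$sensors,
      eval_mode = config$eval_mode,
      k = config$k, train_fraction = config$train_fraction,
      n_windows = nrow(fm),
      n_features_bank = length(registry$name),
      n_features_used = length(features),
      features_used = features,
      stage_timings_s = timings
    )
    jsonlite::write_json(
      manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  say(
    "done in ",
    format(as.numeric(difftime(Sys.time(), t0, units = "secs")), digits = 3),
    " s"
  )
  invisible(list(
    features = fm, selection = selection, reports = reports,
    out_dir = out_dir
  ))
}

#' Summary table across pipeline reports
#'
#' One row per classifier and activity, mirroring the layout of published
#' per-activity accuracy tables, plus overall accuracy.
#'
#' @param reports Named list of `posture_eval` (from [run_pipeline()]).
#' @return Tibble `classifier`, `class`, `accuracy`, `overall`.
#' @export
accuracy_table <- function(reports) {
  rows <- lapply(reports, function(r) {
    mutate(tidy(r), overall = r$overall_accuracy)
  })
  bind_rows(rows)
}
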