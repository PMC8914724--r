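# End-to-end pipeline: simulate -> preprocess -> features -> evaluate ->
# transfer, with a YAML-serializable config and a run manifest so every
# output file is traceable to one configuration and seed.

#' Default pipeline configuration
#'
#' Nested list with one section per stage. The shipped default simulates a
#' six-subject cohort of 20-minute recordings — small enough for
#' continuous-integration runs while exercising every stage.
#'
#' @param seed top-level seed from which all stage randomness flows.
#' @return Nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simulation = list(n_subjects = 6, duration_min = 20,
                      sample_rate_hz = 32),
    ppg = list(cutoff_low_motion_hz = 4, cutoff_high_motion_hz = 2.5,
               smooth_s = 0.25, window_s = 60, bpm_min = 40,
               bpm_max = 180),
    features = list(set = "FEAT1"),
    evaluation = list(models = hydration_methods(), test_fraction = 0.3,
                      n_runs = 10),
    transfer = list(models = c("dnn", "random_forest", "extra_trees"),
                    test_fractions = c(0.3, 0.7), pooled = TRUE)
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults section-wise; missing
#' sections keep their defaults.
#'
#' @param path YAML file.
#' @param seed fallback seed if the file has none.
#' @return Nested configuration list.
#' @export
read_pipeline_config <- function(path, seed = 1L) {
  user <- yaml::read_yaml(path)
  utils::modifyList(default_config(seed), user)
}

#' Per-minute features for one recording (preprocessing stage)
#'
#' Runs clipping/magnitudes/cumulative changes, one-minute aggregation and
#' the PPG beat pipeline, and merges the results.
#'
#' @param recording a `raw_recording`.
#' @param ppg_opts list of [ppg_minute_features()] options.
#' @return Data frame, one row per complete minute.
#' @export
extract_minute_features <- function(recording, ppg_opts = list()) {
  kin <- compute_kinematics(recording)
  minutes <- aggregate_minutes(recording, kin)
  beat <- do.call(ppg_minute_features,
                  c(list(recording = recording, kinematics = kin),
                    ppg_opts))
  merge(minutes, beat, by = "minute_index", sort = TRUE)
}

#' Build the cohort-level feature matrix (feature stage)
#'
#' Applies [extract_minute_features()] per subject, assembles FEAT1 and
#' optionally reduces to FEAT2.
#'
#' @param cohort result of [generate_cohort()] (or an equivalent list of
#'   `profiles` + `recordings`).
#' @param set `"FEAT1"` or `"FEAT2"`.
#' @param ppg_opts options forwarded to the PPG pipeline.
#' @return Feature matrix for all subjects (rows ordered by subject, then
#'   minute).
#' @export
build_feature_matrix <- function(cohort, set = c("FEAT1", "FEAT2"),
                                 ppg_opts = list()) {
  set <- match.arg(set)
  beat_cols <- c("ibi", "bpm", "breathingrate", "RMSSD", "success")
  mats <- lapply(seq_len(nrow(cohort$profiles)), function(i) {
    profile <- cohort$profiles[i, ]
    rec <- cohort$recordings[[profile$subject_id]]
    mf <- extract_minute_features(rec, ppg_opts)
    assemble_feat1(mf[setdiff(names(mf), beat_cols)],
                   mf[c("minute_index", beat_cols)],
                   profile)
  })
  feat1 <- do.call(rbind, mats)
  attr(feat1, "feature_set") <- "FEAT1"
  if (set == "FEAT1") feat1 else assemble_feat2(feat1)
}

#' Run the full pipeline
#'
#' Simulate a cohort, preprocess every recording, assemble the configured
#' feature set, run the model comparison and the transfer-learning
#' personalization. If `outdir` is given, writes per-subject Shimmer CSV
#' exports, the profile sidecar, the feature matrix with a schema file,
#' both reports as CSV, and a `manifest.yaml` (config snapshot, seed,
#' package version, timestamps, output files).
#'
#' @param config configuration list (see [default_config()]).
#' @param outdir optional output directory, created if needed.
#' @param quiet suppress stage messages.
#' @return Invisibly, a list: `cohort`, `features`, `report`,
#'   `transfer`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), outdir = NULL,
                         quiet = FALSE) {
  say <- function(...) if (!quiet) message(...)
  t_start <- Sys.time()
  seed <- config$seed

  say("stage simulate: ", config$simulation$n_subjects, " subject(s)")
  sim_args <- config$simulation
  sim_args$seed <- seed
  cfg <- do.call(sim_config, sim_args)
  cohort <- generate_cohort(cfg)

  say("stage preprocess + features: set ", config$features$set)
  feats <- build_feature_matrix(cohort, config$features$set,
                                ppg_opts = config$ppg)

  say("stage evaluate: ", length(config$evaluation$models), " model(s), ",
      config$evaluation$n_runs, " run(s)")
  report <- run_comparison(feats, models = config$evaluation$models,
                           test_fraction = config$evaluation$test_fraction,
                           n_runs = config$evaluation$n_runs, seed = seed)

  say("stage transfer: ", length(config$transfer$models), " model(s)")
  transfer <- transfer_eval(feats, models = config$transfer$models,
                            test_fractions = config$transfer$test_fractions,
                            seed = seed, pooled = config$transfer$pooled)

  manifest <- list(
    package_version = as.character(utils::packageVersion("hydrowear")),
    seed = seed,
    config = config,
    started = format(t_start, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    outputs = character(0)
  )

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (sid in cohort$profiles$subject_id) {
      f <- file.path(outdir, paste0(sid, "_shimmer.csv"))
      write_shimmer_csv(cohort$recordings[[sid]], f)
      files <- c(files, f)
    }
    f <- file.path(outdir, "profiles.csv")
    write_profiles_csv(cohort$profiles, f)
    files <- c(files, f)
    f <- file.path(outdir, "features.csv")
    utils::write.csv(feats, f, row.names = FALSE)
    files <- c(files, f)
    schema <- file.path(outdir, "features_schema.yaml")
    yaml::write_yaml(list(feature_set = attr(feats, "feature_set"),
                          target = "sinceLastDrinking",
                          features = feature_columns(feats)), schema)
    files <- c(files, schema)
    f <- file.path(outdir, "model_report.csv")
    utils::write.csv(as.data.frame(report), f, row.names = FALSE)
    files <- c(files, f)
    f <- file.path(outdir, "transfer_report.csv")
    utils::write.csv(as.data.frame(transfer), f, row.names = FALSE)
    files <- c(files, f)
    manifest$outputs <- files
    yaml::write_yaml(manifest, file.path(outdir, "manifest.yaml"))
  }

  invisible(list(cohort = cohort, features = feats, report = report,
                 transfer = transfer, manifest = manifest))
}
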