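#!/usr/bin/env Rscript

# Thin command-line wrapper over the hydrowear package.
#
#   Rscript scripts/pipeline.R <subcommand> [options]
#
# Subcommands: simulate | preprocess | features | evaluate | transfer | all
# Every stage consumes only files produced by the previous stage plus the
# configuration, and `all` writes a run manifest alongside its outputs.

suppressPackageStartupMessages({
  library(optparse)
  library(hydrowear)
})

argv <- commandArgs(trailingOnly = TRUE)
sub <- if (length(argv)) argv[1] else ""
known <- c("simulate", "preprocess", "features", "evaluate", "transfer",
           "all")
if (!sub %in% known) {
  cat("usage: Rscript scripts/pipeline.R <",
      paste(known, collapse = "|"), "> [options]\n", sep = "")
  quit(status = 1L)
}

opts <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--config", type = "character", default = NULL,
              help = "YAML config; defaults used when absent"),
  make_option("--indir", type = "character", default = "pipeline_out"),
  make_option("--outdir", type = "character", default = "pipeline_out"),
  make_option("--set", type = "character", default = NULL,
              help = "feature set, FEAT1 or FEAT2")
)), args = argv[-1])

cfg <- if (is.null(opts$config)) default_config(opts$seed) else
  read_pipeline_config(opts$config, opts$seed)
cfg$seed <- opts$seed
if (!is.null(opts$set)) cfg$features$set <- opts$set
dir.create(opts$outdir, recursive = TRUE, showWarnings = FALSE)

read_cohort <- function(dir) {
  profiles <- read_profiles_csv(file.path(dir, "profiles.csv"))
  recs <- lapply(profiles$subject_id, function(sid)
    read_shimmer_csv(file.path(dir, paste0(sid, "_shimmer.csv")), sid))
  names(recs) <- profiles$subject_id
  list(profiles = profiles, recordings = recs)
}

if (sub == "all") {
  run_pipeline(cfg, outdir = opts$outdir)
} else if (sub == "simulate") {
  sim_args <- cfg$simulation
  sim_args$seed <- cfg$seed
  cohort <- generate_cohort(do.call(sim_config, sim_args))
  for (sid in cohort$profiles$subject_id)
    write_shimmer_csv(cohort$recordings[[sid]],
                      file.path(opts$outdir, paste0(sid, "_shimmer.csv")))
  write_profiles_csv(cohort$profiles,
                     file.path(opts$outdir, "profiles.csv"))
} else if (sub == "preprocess") {
  cohort <- read_cohort(opts$indir)
  for (sid in cohort$profiles$subject_id) {
    mf <- extract_minute_features(cohort$recordings[[sid]], cfg$ppg)
    utils::write.csv(mf,
                     file.path(opts$outdir, paste0(sid, "_minutes.csv")),
                     row.names = FALSE)
  }
} else if (sub == "features") {
  cohort <- read_cohort(opts$indir)
  feats <- build_feature_matrix(cohort, cfg$features$set,
                                ppg_opts = cfg$ppg)
  utils::write.csv(feats, file.path(opts$outdir, "features.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(feature_set = attr(feats, "feature_set"),
                        target = "sinceLastDrinking",
                        features = feature_columns(feats)),
                   file.path(opts$outdir, "features_schema.yaml"))
} else if (sub %in% c("evaluate", "transfer")) {
  feats <- utils::read.csv(file.path(opts$indir, "features.csv"),
                           check.names = FALSE)
  if (sub == "evaluate") {
    rep <- run_comparison(feats, models = cfg$evaluation$models,
                          test_fraction = cfg$evaluation$test_fraction,
                          n_runs = cfg$evaluation$n_runs, seed = cfg$seed)
    print(rep)
    utils::write.csv(as.data.frame(rep),
                     file.path(opts$outdir, "model_report.csv"),
                     row.names = FALSE)
  } else {
    tr <- transfer_eval(feats, models = cfg$transfer$models,
                        test_fractions = cfg$transfer$test_fractions,
                        seed = cfg$seed, pooled = cfg$transfer$pooled)
    print(tr)
    utils::write.csv(as.data.frame(tr),
                     file.path(opts$outdir, "transfer_report.csv"),
                     row.names = FALSE)
  }
}
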