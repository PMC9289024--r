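# Shared settings for the numbered analysis scripts. Every script sources
# this file, so the whole analysis is reproducible from one seed.

library(sepsafe)

results_dir <- "results"
dir.create(results_dir, recursive = TRUE, showWarnings = FALSE)

analysis_config <- pipeline_config(
  n_stays = 2000,   # ICU stays in the synthetic cohort
  k = 20,           # patient-state clusters (desk scale)
  seed = 1,
  B = 2000          # bootstrap resamples for the policy values
)

# The trained run is cached under results/ so later scripts do not retrain;
# the cache is safe to delete — runs are deterministic in the config.
get_run <- function(cfg = analysis_config) {
  cache <- file.path(results_dir, "pipeline_run.rds")
  if (file.exists(cache)) {
    run <- readRDS(cache)
    if (identical(run$config, cfg)) return(run)
  }
  run <- run_pipeline(cfg)
  saveRDS(run, cache)
  run
}
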