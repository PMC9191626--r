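# Shared setup for the numbered analysis scripts.
#
# Every script reruns the seeded pipeline up to the stage it reports on;
# because all stages are deterministic given (config, seed), the scripts can
# be run independently. A cache under scratch/ avoids recomputation when the
# scripts are run in order.

library(inflammaging)

ANALYSIS_SEED <- 20260101L
RESULTS_DIR <- "results"
CACHE_FILE <- file.path("scratch", "pipeline_cache.rds")
dir.create(RESULTS_DIR, showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

analysis_config <- function() {
  pipeline_config(seed = ANALYSIS_SEED, output_dir = RESULTS_DIR)
}

# run (or reuse) the full pipeline report
get_report <- function() {
  cfg <- analysis_config()
  if (file.exists(CACHE_FILE)) {
    cached <- readRDS(CACHE_FILE)
    if (identical(cached$config$seed, cfg$seed)) return(cached)
  }
  rep <- run_pipeline(cfg)
  saveRDS(rep, CACHE_FILE)
  rep
}

say <- function(...) cat(sprintf(...), "\n")
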