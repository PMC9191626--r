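# Simulate the synthetic atherosclerosis cohort: four strata (healthy
# young/old, diseased young/old) across four batches, with a planted
# age -> inflammation -> disease mediation chain, and write it to disk.

source("analysis/00_common.R")

cfg <- cohort_config(seed = ANALYSIS_SEED)
study <- generate_cohort(cfg)

say("cohort: %d genes x %d samples (%d train / %d test)",
    nrow(study$expression), ncol(study$expression),
    sum(study$split == "train"), sum(study$split == "test"))
say("strata: healthy young %d, healthy old %d, diseased young %d, diseased old %d",
    sum(study$disease == 0 & study$age <= 50), sum(study$disease == 0 & study$age > 50),
    sum(study$disease == 1 & study$age <= 50), sum(study$disease == 1 & study$age > 50))
say("planted roles: %s",
    paste(names(table(study$truth$role)), table(study$truth$role), collapse = ", "))
say("zero fraction (dropout + fill): %.3f", mean(study$expression == 0))

files <- write_study(study, file.path(RESULTS_DIR, "cohort"))
say("wrote %s", paste(files, collapse = ", "))
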