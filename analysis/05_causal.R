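# Expression-based Mendelian-randomization cascade: stratify the training
# samples by inflammation level, then filter aging -> inflamm-aging marker
# pairs through the instrument, permutation, outcome, weak-instrument, and
# pleiotropy stages.

source("analysis/00_common.R")

rep <- get_report()
cp <- rep$causal
part <- attr(cp, "partition")
say("stratification: %s", paste(names(table(part)), table(part), collapse = ", "))
say("tested pairs: %d; retained causal pairs: %d", nrow(cp), sum(cp$retained))
rp <- retained_pairs(cp)
say("distinct instruments (aging markers): %d; distinct outcomes: %d",
    length(unique(rp$aging_marker)), length(unique(rp$disease_marker)))
say("largest |corr - pcorr| contrast: %.3f (pair %s -> %s)",
    rp$diff[1], rp$aging_marker[1], rp$disease_marker[1])
say("pair table: %s", file.path(RESULTS_DIR, "causal_pairs.tsv"))
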