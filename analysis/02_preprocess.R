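# Preprocess the cohort: zero-gene filtering, outlier-triggered log2
# transform, z-scoring against healthy-aged training samples, removal of the
# top three reference SVD components (batch axes), and final z-scoring.

source("analysis/00_common.R")

study <- read_study(file.path(RESULTS_DIR, "cohort"))
pp <- preprocess(study)

say("genes before/after zero filtering and reference scaling: %d -> %d",
    nrow(study$expression), nrow(pp$expression))
ref <- pp$disease == 0 & pp$age > 50 & pp$split == "train"
say("reference (healthy aged, train): %d samples", sum(ref))
say("per-gene reference mean/sd after the chain: %.3f / %.3f",
    mean(rowMeans(pp$expression[, ref])), mean(apply(pp$expression[, ref], 1, sd)))

# how much batch structure is left?
bvar <- function(X) mean(apply(X, 1, function(v) {
  summary(lm(v ~ factor(study$batch)))$r.squared
}))
say("mean per-gene batch R^2, raw vs preprocessed: %.3f -> %.3f",
    bvar(log2(study$expression + 1)[rownames(pp$expression)[1:50], ]),
    bvar(pp$expression[1:50, ]))
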