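# Metropolis-Hastings sensitivity analysis: sample marker states from
# group-conditioned posteriors and flag pairs whose sign-product frequency
# in the low-inflammation healthy group lies strictly between the other two
# groups.

source("analysis/00_common.R")

rep <- get_report()
sn <- rep$sensitivity
acc <- attr(sn, "acceptance_rates")
say("MH acceptance rates per group: %s",
    paste(names(acc), round(acc, 2), sep = "=", collapse = ", "))
say("sensitive pairs: %d of %d MR-retained", sum(sn$sensitive), nrow(sn))
top <- head(as.data.frame(sn)[sn$sensitive, ], 3)
for (i in seq_len(nrow(top)))
  say("  %s -> %s: freqs %.2f / %.2f / %.2f, diff %.2f",
      top$aging_marker[i], top$disease_marker[i], top$freq_low[i],
      top$freq_highH[i], top$freq_dis[i], top$diff[i])
say("sensitivity table: %s", file.path(RESULTS_DIR, "sensitivity.tsv"))
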