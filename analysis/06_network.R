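# Score-conditioned differential co-expression network over the model
# markers: sign-flip edges, scale-free check, train-vs-test validation, and
# shortest paths for the retained causal pairs.

source("analysis/00_common.R")

rep <- get_report()
net <- rep$network_train
say("network: %d nodes (%d connected), %d edges",
    length(net$degree), sum(net$degree > 0), nrow(net$edges))
say("log-log degree-frequency correlation: r = %.3f (p = %.3g)",
    rep$scale_free$r, rep$scale_free$p_value)
if (!is.null(rep$validation))
  say("train vs test edge overlap, one-sided Fisher p = %.3g",
      rep$validation$p_value)
say("shortest paths found for %d of %d retained pairs",
    length(rep$paths$paths), sum(rep$causal$retained))
say("path length distribution (edges): %s",
    paste(names(table(rep$paths$lengths)), table(rep$paths$lengths),
          sep = "x", collapse = ", "))
say("edge table: %s", file.path(RESULTS_DIR, "network_edges_train.tsv"))
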