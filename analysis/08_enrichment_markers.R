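# Hypergeometric enrichment of the aging -> inflamm-aging shortest paths
# against the fixture gene-set collection, and betweenness-based network
# markers with a permutation null.
#
# Enrichment is demonstrated on a transcriptome-scale cohort (1000 genes,
# same planted structure): the hypergeometric test is only informative when
# the gene sets are a small fraction of the universe.

source("analysis/00_common.R")

rep <- get_report()
say("-- network markers (default cohort) --")
nm <- rep$network_markers
print(head(nm, 8))
truth <- rep$study_raw$truth
axis <- truth$gene_id[truth$role %in% c("aging", "inflammation")]
say("top-betweenness genes in the planted mediation axis: %d of %d",
    sum(head(nm$gene, 10) %in% axis), min(10, nrow(nm)))

say("-- path enrichment (transcriptome-scale cohort) --")
big <- generate_cohort(cohort_config(n_genes = 1000, seed = ANALYSIS_SEED))
pp <- preprocess(big)
bt <- pp$truth
aging <- intersect(bt$gene_id[bt$role == "aging"], rownames(pp$expression))
med <- intersect(bt$gene_id[bt$role == "inflammation"], rownames(pp$expression))
sc <- score_study(pp, med, "aging")
trn <- pp$split == "train"
es <- groupwise_edge_statistics(pp$expression[c(aging, med), trn], sc[trn],
                                pp$disease[trn])
net <- build_differential_network(es)
paths <- shortest_paths_for_pairs(
  net, expand.grid(aging_marker = aging, disease_marker = med,
                   stringsAsFactors = FALSE))
sets <- truth_gene_sets(big, n_decoys = 5, seed = ANALYSIS_SEED)
res <- enrich_paths(paths$paths, sets, rownames(pp$expression))
print(res$results)
write.table(res$results, file.path(RESULTS_DIR, "enrichment_transcriptome.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
say("top term by enrichment score: %s",
    res$results$term[order(-res$results$score)][1])
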