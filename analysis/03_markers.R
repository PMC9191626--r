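# Fit the improved inflamm-aging marker model: interaction features, ReliefF
# ranking, cosine-kNN cross-validation, and the five-step integration of
# aging, inflammatory, and disease markers.

source("analysis/00_common.R")

rep <- get_report()
mm <- rep$marker_model
say("aging markers: %d, inflammatory (inflamm-aging) markers: %d, disease markers: %d",
    length(mm$aging_markers), length(mm$inflammatory_markers),
    length(mm$disease_markers))
say("disease-model CV accuracy over feature counts: %s",
    paste(names(mm$cv_curve), round(mm$cv_curve, 3), sep = "=", collapse = ", "))
say("chosen feature count: %d", mm$chosen_count)

truth <- rep$study_raw$truth
role <- function(g) truth$role[match(g, truth$gene_id)]
say("planted-role composition of the inflammatory markers: %s",
    paste(names(table(role(mm$inflammatory_markers))),
          table(role(mm$inflammatory_markers)), collapse = ", "))
say("marker table: %s", file.path(RESULTS_DIR, "markers_selected.tsv"))
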