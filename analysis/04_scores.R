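# Compute the kNN-distance inflamm-aging score, adjust it by age, and test
# the accelerated inflamm-aging pattern in the diseased group.

source("analysis/00_common.R")

rep <- get_report()
tab <- rep$scores
say("inflamm-aging score: mean healthy %.3f vs diseased %.3f",
    mean(tab$raw_score[tab$disease == 0]), mean(tab$raw_score[tab$disease == 1]))
say("Kruskal-Wallis disease vs healthy, raw score: H = %.2f, p = %.3g",
    rep$score_tests$raw$statistic, rep$score_tests$raw$p_value)
say("Kruskal-Wallis disease vs healthy, age-adjusted: H = %.2f, p = %.3g",
    rep$score_tests$adjusted$statistic, rep$score_tests$adjusted$p_value)
say("age-regression coefficient b = %.3f", attr(tab, "b"))
say("score table: %s", file.path(RESULTS_DIR, "scores.tsv"))
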