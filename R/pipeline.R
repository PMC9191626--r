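## End-to-end orchestration: generate -> preprocess -> predictors -> score
## -> causal -> network -> sensitivity -> enrich -> markers, from a single
## declarative configuration with seeded per-stage substreams.

#' Full pipeline configuration
#'
#' @param cohort A [cohort_config()] (used when no study is supplied).
#' @param preprocess A [preprocess_params()].
#' @param predictor A [predictor_config()].
#' @param causal A [causal_params()].
#' @param m_neighbors Score neighbors (default 9).
#' @param n_mcmc_samples Post-burn-in MH samples per group.
#' @param n_marker_perm Permutations of the betweenness null.
#' @param enrich_p_max,enrich_fdr_max Enrichment thresholds.
#' @param genesets Named list of gene sets, a GMT path, or NULL to derive
#'   synthetic truth-based sets from the generated cohort.
#' @param stages Character vector of stages to run (prefix order enforced).
#' @param seed Global seed; each stage derives its own substream.
#' @param output_dir Directory for serialized outputs, or NULL to skip
#'   writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            preprocess = preprocess_params(),
                            predictor = predictor_config(),
                            causal = causal_params(),
                            m_neighbors = 9,
                            n_mcmc_samples = 1000,
                            n_marker_perm = 1000,
                            enrich_p_max = 0.05,
                            enrich_fdr_max = 0.1,
                            genesets = NULL,
                            stages = c("generate", "preprocess", "predictors",
                                       "score", "causal", "network",
                                       "sensitivity", "enrich", "markers"),
                            seed = 1L,
                            output_dir = NULL) {
  cfg <- structure(as.list(environment()), class = "pipeline_config")
  errs <- validate_config(cfg)
  if (length(errs)) stop("invalid pipeline_config:\n  - ",
                         paste(errs, collapse = "\n  - "))
  cfg
}

#' Validate a pipeline configuration
#'
#' Checks every invariant of every referenced parameter object and returns
#' the full list of violations (empty when valid); nothing is silently
#' fixed.
#'
#' @param config A `pipeline_config` (or plain list with the same fields).
#' @return Character vector of violation messages (length 0 = ok).
#' @export
validate_config <- function(config) {
  errs <- character(0)
  chk <- function(expr, msg) if (!isTRUE(expr)) errs <<- c(errs, msg)
  t1 <- tryCatch({ validate_cohort_config(config$cohort); NULL },
                 error = function(e) conditionMessage(e))
  if (!is.null(t1)) errs <- c(errs, t1)
  pp <- config$preprocess
  chk(pp$zero_fraction_threshold >= 0 && pp$zero_fraction_threshold <= 1,
      "zero_fraction_threshold must lie in [0,1]")
  chk(pp$outlier_sd_multiplier > 0, "outlier_sd_multiplier must be positive")
  chk(pp$n_svd_components >= 0, "n_svd_components must be non-negative")
  pc <- config$predictor
  chk(pc$k_neighbors >= 1, "k_neighbors must be positive")
  chk(pc$n_folds >= 2, "n_folds must be >= 2")
  ca <- config$causal
  chk(ca$n_perm >= 100, "causal n_perm must be >= 100")
  chk(ca$perm_p_max > 0 && ca$perm_p_max <= 1, "perm_p_max must lie in (0,1]")
  chk(config$m_neighbors >= 1, "m_neighbors must be positive")
  chk(config$n_mcmc_samples >= 1, "n_mcmc_samples must be positive")
  chk(config$n_marker_perm >= 1, "n_marker_perm must be positive")
  known <- c("generate", "preprocess", "predictors", "score", "causal",
             "network", "sensitivity", "enrich", "markers")
  chk(all(config$stages %in% known),
      paste("unknown stage(s):",
            paste(setdiff(config$stages, known), collapse = ", ")))
  errs
}

#' Provenance header written at the top of every output file
#' @noRd
output_header <- function(config) {
  sprintf("# inflammaging %s | config %s | seed %d",
          as.character(utils::packageVersion("inflammaging")),
          config_hash(config[setdiff(names(config), "output_dir")]),
          config$seed)
}

#' @noRd
write_stage_tsv <- function(df, file, config) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(output_header(config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full inflamm-aging pipeline
#'
#' Executes the enabled stages in order on a synthetic cohort (or a caller-
#' supplied study), each stage consuming the previous stage's outputs.
#' Stage randomness is drawn from substreams derived from the global seed,
#' so a given (config, seed) always reproduces the same report.
#'
#' @param config A [pipeline_config()].
#' @param study Optional `expression_study`; when NULL the `generate` stage
#'   builds one from `config$cohort`.
#' @return A `pipeline_report` list with per-stage artifacts and a `summary`
#'   of marker counts, pair counts, network size, sensitive pairs, top
#'   terms, top markers, and headline p-values.
#' @export
run_pipeline <- function(config = pipeline_config(), study = NULL) {
  errs <- validate_config(config)
  if (length(errs)) stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "))
  stages <- config$stages
  need <- function(stage, artifact, from) {
    if (is.null(artifact))
      stop("stage '", stage, "' requires output of stage '", from,
           "' which did not run")
    artifact
  }
  out <- list(config = config)
  dir_out <- config$output_dir
  if (!is.null(dir_out) && !dir.exists(dir_out))
    dir.create(dir_out, recursive = TRUE)

  if ("generate" %in% stages && is.null(study)) {
    cc <- config$cohort
    cc$seed <- substream_seed(config$seed, "generate")
    study <- generate_cohort(cc)
  }
  if (is.null(study)) stop("stage 'preprocess' requires a study: enable 'generate' or pass one")
  out$study_raw <- study

  if ("preprocess" %in% stages) {
    study <- preprocess(study, config$preprocess)
    out$study <- study
  }

  genesets <- config$genesets
  if (is.character(genesets)) genesets <- read_gmt(genesets)
  if (is.null(genesets) && !is.null(out$study_raw$truth))
    genesets <- truth_gene_sets(out$study_raw,
                                seed = substream_seed(config$seed, "genesets"))

  if ("predictors" %in% stages) {
    st <- need("predictors", out$study, "preprocess")
    pc <- config$predictor
    pc$seed <- substream_seed(config$seed, "predictors")
    aging_sel <- select_markers(st, "aging", pc)
    disease_sel <- select_markers(st, "disease", pc)
    inflam_set <- genesets[[grep("INFLAMMATORY", names(genesets), value = TRUE)[1] %||%
                              names(genesets)[1]]]
    ## candidate pools go deep into the rankings; the improved model's
    ## Kruskal-Wallis and re-selection stages shape the final sets
    out$marker_model <- build_improved_model(
      st, inflam_set,
      utils::head(aging_sel$ranking, max(80L, length(aging_sel$markers))),
      utils::head(disease_sel$ranking, max(160L, length(disease_sel$markers))),
      pc)
    out$aging_selection <- aging_sel
    out$disease_selection <- disease_sel
    if (!is.null(dir_out)) {
      write_stage_tsv(data.frame(
        set = rep(c("aging", "inflammatory", "disease"),
                  times = c(length(out$marker_model$aging_markers),
                            length(out$marker_model$inflammatory_markers),
                            length(out$marker_model$disease_markers))),
        gene = c(out$marker_model$aging_markers,
                 out$marker_model$inflammatory_markers,
                 out$marker_model$disease_markers)),
        file.path(dir_out, "markers_selected.tsv"), config)
    }
  }

  if ("score" %in% stages) {
    st <- need("score", out$study, "preprocess")
    mm <- need("score", out$marker_model, "predictors")
    raw <- score_study(st, mm$inflammatory_markers, "aging", config$m_neighbors)
    tab <- adjust_by_age(raw, st$age, fit_group = st$disease == 0)
    tab$disease_score <- score_study(st, mm$disease_markers, "disease",
                                     config$m_neighbors)
    tab$disease <- st$disease
    tab$split <- st$split
    out$scores <- tab
    out$score_tests <- list(
      raw = compare_groups(tab$raw_score, st$disease),
      adjusted = compare_groups(tab$adjusted_score, st$disease)
    )
    if (!is.null(dir_out))
      write_stage_tsv(tab, file.path(dir_out, "scores.tsv"), config)
  }

  if ("causal" %in% stages) {
    st <- need("causal", out$study, "preprocess")
    mm <- need("causal", out$marker_model, "predictors")
    sc <- need("causal", out$scores, "score")
    ca <- config$causal
    ca$seed <- substream_seed(config$seed, "causal")
    ## outcome variables are the inflamm-aging markers (the aging model's
    ## instruments against the inflammatory-family outcomes)
    out$causal <- run_causal_cascade(
      st, stats::setNames(sc$raw_score, sc$sample),
      mm$aging_markers, mm$inflammatory_markers, mm$inflammatory_markers, ca)
    if (!is.null(dir_out))
      write_stage_tsv(as.data.frame(out$causal),
                      file.path(dir_out, "causal_pairs.tsv"), config)
  }

  if ("network" %in% stages) {
    st <- need("network", out$study, "preprocess")
    sc <- need("network", out$scores, "score")
    mm <- need("network", out$marker_model, "predictors")
    tr <- st$split == "train"
    te <- st$split == "test"
    ## network over the model's marker space
    net_genes <- intersect(unique(c(mm$aging_markers, mm$inflammatory_markers,
                                    mm$disease_markers)),
                           rownames(st$expression))
    mk_net <- function(sel) {
      es <- groupwise_edge_statistics(st$expression[net_genes, sel, drop = FALSE],
                                      sc$raw_score[sel], st$disease[sel])
      build_differential_network(es)
    }
    out$network_train <- mk_net(tr)
    out$network_test <- if (sum(te) >= 8 && length(unique(st$disease[te])) == 2)
      mk_net(te) else NULL
    out$scale_free <- tryCatch(scale_free_check(out$network_train),
                               error = function(e) list(r = NA_real_,
                                                        p_value = NA_real_,
                                                        error = conditionMessage(e)))
    out$validation <- if (!is.null(out$network_test))
      tryCatch(cross_cohort_validation(out$network_train, out$network_test),
               error = function(e) list(p_value = NA_real_,
                                        error = conditionMessage(e))) else NULL
    if (!is.null(out$causal)) {
      out$paths <- shortest_paths_for_pairs(out$network_train,
                                            retained_pairs(out$causal))
    }
    if (!is.null(dir_out))
      write_stage_tsv(out$network_train$edges,
                      file.path(dir_out, "network_edges_train.tsv"), config)
  }

  if ("sensitivity" %in% stages) {
    st <- need("sensitivity", out$study, "preprocess")
    mm <- need("sensitivity", out$marker_model, "predictors")
    cp <- need("sensitivity", out$causal, "causal")
    out$sensitivity <- run_sensitivity(
      st, attr(cp, "partition"), retained_pairs(cp), mm,
      n_samples = config$n_mcmc_samples, m_neighbors = config$m_neighbors,
      seed = substream_seed(config$seed, "sensitivity"))
    if (!is.null(dir_out))
      write_stage_tsv(as.data.frame(out$sensitivity),
                      file.path(dir_out, "sensitivity.tsv"), config)
  }

  if ("enrich" %in% stages) {
    st <- need("enrich", out$study, "preprocess")
    pth <- need("enrich", out$paths, "network")
    out$enrichment <- enrich_paths(pth$paths, genesets, rownames(st$expression),
                                   config$enrich_p_max, config$enrich_fdr_max)
    if (!is.null(dir_out))
      write_stage_tsv(out$enrichment$results,
                      file.path(dir_out, "enrichment.tsv"), config)
  }

  if ("markers" %in% stages) {
    pth <- need("markers", out$paths, "network")
    net <- need("markers", out$network_train, "network")
    btw <- path_betweenness(pth$paths)
    out$network_markers <- if (nrow(btw) && length(pth$paths))
      betweenness_permutation(net, btw, n_pairs = length(pth$paths),
                              n_perm = config$n_marker_perm,
                              seed = substream_seed(config$seed, "markers"))
    else btw
    if (!is.null(dir_out) && nrow(btw))
      write_stage_tsv(out$network_markers,
                      file.path(dir_out, "network_markers.tsv"), config)
  }

  out$summary <- pipeline_summary(out)
  if (!is.null(dir_out)) {
    rep_file <- file.path(dir_out, "report.txt")
    writeLines(c(output_header(config), format_report(out$summary)), rep_file)
  }
  structure(out, class = "pipeline_report")
}

#' @noRd
pipeline_summary <- function(out) {
  mm <- out$marker_model
  s <- list(
    n_genes = if (!is.null(out$study)) nrow(out$study$expression) else NA,
    n_samples = if (!is.null(out$study)) ncol(out$study$expression) else NA,
    n_aging_markers = if (!is.null(mm)) length(mm$aging_markers) else NA,
    n_inflammatory_markers = if (!is.null(mm)) length(mm$inflammatory_markers) else NA,
    n_disease_markers = if (!is.null(mm)) length(mm$disease_markers) else NA,
    cv_accuracy = if (!is.null(mm)) max(mm$cv_curve) else NA,
    score_kw_p_raw = if (!is.null(out$score_tests)) out$score_tests$raw$p_value else NA,
    score_kw_p_adjusted = if (!is.null(out$score_tests)) out$score_tests$adjusted$p_value else NA,
    n_causal_pairs = if (!is.null(out$causal)) sum(out$causal$retained) else NA,
    n_network_edges = if (!is.null(out$network_train)) nrow(out$network_train$edges) else NA,
    scale_free_r = if (!is.null(out$scale_free)) out$scale_free$r else NA,
    validation_fisher_p = if (!is.null(out$validation)) out$validation$p_value else NA,
    n_paths = if (!is.null(out$paths)) length(out$paths$paths) else NA,
    n_sensitive_pairs = if (!is.null(out$sensitivity)) sum(out$sensitivity$sensitive) else NA,
    top_terms = if (!is.null(out$enrichment) && nrow(out$enrichment$results))
      utils::head(out$enrichment$results$term, 3) else character(0),
    top_markers = if (!is.null(out$network_markers) && nrow(out$network_markers))
      utils::head(out$network_markers$gene, 5) else character(0)
  )
  s
}

#' @noRd
format_report <- function(s) {
  fmt <- function(x) if (is.numeric(x)) format(x, digits = 6) else
    paste(x, collapse = ", ")
  c("inflamm-aging pipeline report",
    vapply(names(s), function(k) sprintf("%-24s %s", k, fmt(s[[k]])), character(1)))
}

#' @export
print.pipeline_report <- function(x, ...) {
  writeLines(format_report(x$summary))
  invisible(x)
}
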