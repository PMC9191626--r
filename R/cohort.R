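## Synthetic multi-batch expression cohorts with a planted
## age -> inflammation -> disease (atherosclerosis) causal chain.

#' Configuration for a synthetic inflamm-aging cohort
#'
#' Describes a merged multi-batch expression cohort with four strata
#' (healthy young/old, diseased young/old) and three planted gene classes:
#' "aging" genes drifting with biological age, "inflammation" genes
#' downstream of the aging signal (mediators), and "disease" genes
#' downstream of inflammation with a direct disease shift. Remaining genes
#' are pure noise.
#'
#' The mediation chain follows an immune-homeostasis model. Biological age
#' is chronological age plus an individual dispersion term. In healthy
#' samples the inflammatory program activates only above a biological-age
#' threshold (hinge coupling): low-inflammation healthy samples are
#' essentially decoupled from the aging signal, high-inflammation healthy
#' samples are strongly coupled. Atherosclerosis elevates the inflammatory
#' level but inverts the aging coupling (immunosenescent exhaustion), so
#' the three analysis strata (inf-ath-, inf+ath-, inf+ath+) carry distinct,
#' well-separated aging-inflammation coupling regimes — the structure the
#' downstream causal cascade is designed to detect.
#'
#' @param n_genes Total number of genes.
#' @param group_sizes Training-split sizes, in order healthy-young,
#'   healthy-old, diseased-young, diseased-old.
#' @param test_sizes Test-split sizes in the same order; default is one
#'   fifth of the training sizes (rounded).
#' @param n_aging_genes,n_inflammation_genes,n_disease_genes Planted marker
#'   counts; the rest of the genes are null.
#' @param effect_age Loading of aging genes on biological age (log2 units
#'   per biological-age unit).
#' @param effect_mediation Coupling strength along the chain: hinge slope of
#'   the healthy inflammatory response on the aging program and (sign
#'   inverted) slope in disease; likewise for the inflammation -> disease
#'   link. Averaged over healthy samples the effective weight is roughly
#'   half this (the hinge is inactive below threshold), so healthy coupling
#'   is reduced relative to disease.
#' @param effect_direct Direct (non-mediated) disease elevation of the
#'   disease-gene program.
#' @param noise_sd Per-gene residual standard deviation.
#' @param n_batches Number of batches; samples are assigned cyclically.
#' @param batch_sd SD of additive per-batch, per-gene offsets.
#' @param dropout_rate Probability that any matrix cell is zeroed.
#' @param baseline Baseline log2 intensity; matrices are emitted on the
#'   linear scale as 2^(baseline + signal + noise), the distribution shape
#'   of real microarray intensities.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_genes = 200,
                          group_sizes = c(60, 100, 30, 100),
                          test_sizes = NULL,
                          n_aging_genes = 30,
                          n_inflammation_genes = 40,
                          n_disease_genes = 20,
                          effect_age = 1.8,
                          effect_mediation = 0.8,
                          effect_direct = 0.5,
                          noise_sd = 1.0,
                          n_batches = 4,
                          batch_sd = 2.0,
                          dropout_rate = 0.02,
                          baseline = 8,
                          seed = 1L) {
  if (is.null(test_sizes)) test_sizes <- round(group_sizes / 5)
  cfg <- structure(list(
    n_genes = as.integer(n_genes),
    group_sizes = as.integer(group_sizes),
    test_sizes = as.integer(test_sizes),
    n_aging_genes = as.integer(n_aging_genes),
    n_inflammation_genes = as.integer(n_inflammation_genes),
    n_disease_genes = as.integer(n_disease_genes),
    effect_age = effect_age,
    effect_mediation = effect_mediation,
    effect_direct = effect_direct,
    noise_sd = noise_sd,
    n_batches = as.integer(n_batches),
    batch_sd = batch_sd,
    dropout_rate = dropout_rate,
    baseline = baseline,
    seed = as.integer(seed)
  ), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' @noRd
validate_cohort_config <- function(cfg) {
  with(cfg, {
    if (n_genes < 1) stop("configuration error: n_genes must be positive")
    if (length(group_sizes) != 4 || length(test_sizes) != 4)
      stop("configuration error: group_sizes and test_sizes must have length 4")
    if (any(group_sizes < 0) || any(test_sizes < 0))
      stop("configuration error: negative group sizes")
    if (any(c(n_aging_genes, n_inflammation_genes, n_disease_genes) < 0))
      stop("configuration error: negative marker-gene counts")
    if (n_aging_genes + n_inflammation_genes + n_disease_genes > n_genes)
      stop("configuration error: marker-gene counts exceed n_genes")
    if (noise_sd <= 0) stop("configuration error: noise_sd must be positive")
    if (n_batches < 1) stop("configuration error: n_batches must be positive")
    if (batch_sd < 0) stop("configuration error: batch_sd must be non-negative")
    if (dropout_rate < 0 || dropout_rate > 1)
      stop("configuration error: dropout_rate must lie in [0,1]")
  })
  invisible(cfg)
}

#' Generate a synthetic expression cohort
#'
#' Draws ages uniformly on \[20, 50\] (young) and \[51, 85\] (old), plants the
#' aging -> inflammation -> disease chain described in [cohort_config()], adds
#' per-batch gene offsets and dropout zeros, and returns an `expression_study`.
#' Ground-truth gene roles are carried in a separate `truth` table so no
#' downstream stage can read them from the expression matrix.
#'
#' @param config A [cohort_config()].
#' @return An `expression_study`: list with `expression` (genes x samples
#'   matrix), `gene_ids`, `sample_ids`, `age`, `disease`, `batch`, `split`,
#'   and `truth` (data.frame gene_id/role).
#' @export
generate_cohort <- function(config) {
  validate_cohort_config(config)
  cfg <- config
  with_seed(cfg$seed, {
    n_strata <- c("healthy_young", "healthy_old", "diseased_young", "diseased_old")
    counts <- rbind(train = cfg$group_sizes, test = cfg$test_sizes)
    split <- rep(rep(c("train", "test"), each = 4), times = as.vector(t(counts)))
    stratum <- rep(rep(n_strata, 2), times = as.vector(t(counts)))
    ## re-order: train block then test block, strata in order within each
    ord <- order(match(split, c("train", "test")), match(stratum, n_strata))
    split <- split[ord]; stratum <- stratum[ord]
    n_samp <- length(stratum)
    if (n_samp < 4) stop("configuration error: need at least 4 samples overall")

    young <- grepl("young", stratum)
    disease <- as.integer(grepl("diseased", stratum))
    age <- numeric(n_samp)
    age[young] <- stats::runif(sum(young), 20, 50)
    age[!young] <- stats::runif(sum(!young), 51, 85)

    sample_ids <- sprintf("s%04d", seq_len(n_samp))
    gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))

    ## planted roles on a shuffled gene order
    roles <- rep("null", cfg$n_genes)
    shuffled <- sample.int(cfg$n_genes)
    idx_aging <- shuffled[seq_len(cfg$n_aging_genes)]
    idx_inf <- shuffled[cfg$n_aging_genes + seq_len(cfg$n_inflammation_genes)]
    idx_dis <- shuffled[cfg$n_aging_genes + cfg$n_inflammation_genes +
                          seq_len(cfg$n_disease_genes)]
    roles[idx_aging] <- "aging"
    roles[idx_inf] <- "inflammation"
    roles[idx_dis] <- "disease"

    ## biological age: chronological scale (0 at 20y, ~2.2 at 85y) plus
    ## individual dispersion — some 60-year-olds are biologically 75
    a_scale <- (age - 20) / 30
    bio <- a_scale + stats::rnorm(n_samp, 0, 0.6)
    ## hinge threshold: inflammatory program activates past biological
    ## age ~50; disease elevates the level and inverts the coupling
    theta_inf <- 1.0
    theta_dis <- 0.3
    ## inflammatory-level elevation in disease, proportional to the
    ## mediation strength (0.88 at the default 0.8) so null chains stay null
    i0 <- 1.1 * cfg$effect_mediation
    marker_loading <- 1.8

    X <- matrix(stats::rnorm(cfg$n_genes * n_samp, 0, cfg$noise_sd),
                nrow = cfg$n_genes, dimnames = list(gene_ids, sample_ids))

    if (cfg$n_aging_genes > 0) {
      X[idx_aging, ] <- X[idx_aging, , drop = FALSE] +
        matrix(cfg$effect_age * bio, cfg$n_aging_genes, n_samp, byrow = TRUE)
      aging_program <- colMeans(X[idx_aging, , drop = FALSE]) /
        if (cfg$effect_age > 0) cfg$effect_age else 1
    } else aging_program <- bio

    w1 <- stats::rnorm(n_samp, 0, 0.2)
    inf_latent <- cfg$effect_mediation * pmax(aging_program - theta_inf, 0) + w1
    is_dis <- disease == 1
    if (any(is_dis)) {
      inf_latent[is_dis] <- i0 -
        cfg$effect_mediation * (aging_program[is_dis] - mean(aging_program[is_dis])) +
        w1[is_dis]
    }
    if (cfg$n_inflammation_genes > 0) {
      X[idx_inf, ] <- X[idx_inf, , drop = FALSE] +
        matrix(marker_loading * inf_latent, cfg$n_inflammation_genes, n_samp,
               byrow = TRUE)
      inf_program <- colMeans(X[idx_inf, , drop = FALSE]) / marker_loading
    } else inf_program <- inf_latent

    ## immune-dysregulation channel: in disease, aging and inflammation
    ## genes gain a shared direct co-regulation latent with random per-gene
    ## signs (scaled by the mediation strength). The signs cancel in marker
    ## averages, so scores are untouched, but gene-pair correlations gain a
    ## disease-specific direct component that survives score conditioning —
    ## the structure the sign-flip differential-network rule detects.
    if (any(is_dis) && cfg$effect_mediation > 0 &&
        cfg$n_aging_genes + cfg$n_inflammation_genes > 0) {
      h <- stats::rnorm(n_samp)
      l_h <- 1.5 * cfg$effect_mediation
      idx_h <- c(idx_aging, idx_inf)
      signs <- sample(c(-1, 1), length(idx_h), replace = TRUE)
      X[idx_h, is_dis] <- X[idx_h, is_dis, drop = FALSE] +
        (l_h * signs) %o% h[is_dis]
    }

    w2 <- stats::rnorm(n_samp, 0, 0.2)
    dis_latent <- cfg$effect_mediation * pmax(inf_program - theta_dis, 0) + w2
    if (any(is_dis)) {
      dis_latent[is_dis] <- cfg$effect_direct +
        cfg$effect_mediation * (inf_program[is_dis] - mean(inf_program[is_dis])) +
        w2[is_dis]
    }
    if (cfg$n_disease_genes > 0) {
      X[idx_dis, ] <- X[idx_dis, , drop = FALSE] +
        matrix(marker_loading * dis_latent, cfg$n_disease_genes, n_samp,
               byrow = TRUE)
    }

    batch <- ((seq_len(n_samp) - 1L) %% cfg$n_batches) + 1L
    if (cfg$batch_sd > 0 && cfg$n_batches > 1) {
      offsets <- matrix(stats::rnorm(cfg$n_genes * cfg$n_batches, 0, cfg$batch_sd),
                        nrow = cfg$n_genes)
      X <- X + offsets[, batch, drop = FALSE]
    }

    ## emit linear-scale intensities (log-normal), as microarray matrices
    ## are distributed; the log2 signal above is recovered by the
    ## preprocessing chain's outlier-triggered log transform
    X <- 2^(X + cfg$baseline)
    if (cfg$dropout_rate > 0) {
      drop_mask <- matrix(stats::runif(length(X)) < cfg$dropout_rate,
                          nrow = nrow(X))
      X[drop_mask] <- 0
    }

    new_expression_study(
      expression = X, age = age, disease = disease,
      batch = paste0("b", batch), split = split,
      truth = data.frame(gene_id = gene_ids, role = roles,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Construct an expression study container
#'
#' @param expression Numeric genes x samples matrix with unique dimnames.
#' @param age Non-negative numeric per sample (years).
#' @param disease Binary (0/1) per sample.
#' @param batch Character per sample.
#' @param split Character per sample ("train"/"test").
#' @param truth Optional data.frame with columns gene_id, role.
#' @return An `expression_study` list.
#' @export
new_expression_study <- function(expression, age, disease, batch = NULL,
                                 split = NULL, truth = NULL) {
  expression <- as.matrix(expression)
  n <- ncol(expression)
  if (nrow(expression) > 0 && is.null(rownames(expression)))
    stop("expression matrix must carry gene dimnames")
  if (is.null(rownames(expression))) rownames(expression) <- character(0)
  if (is.null(colnames(expression)))
    stop("expression matrix must carry sample dimnames")
  if (anyDuplicated(rownames(expression))) stop("duplicate gene ids")
  if (anyDuplicated(colnames(expression))) stop("duplicate sample ids")
  if (any(!is.finite(expression))) stop("expression contains missing/non-finite entries")
  stopifnot(length(age) == n, length(disease) == n)
  if (any(age < 0)) stop("age must be non-negative")
  if (!all(disease %in% c(0, 1))) stop("disease must be binary 0/1")
  structure(list(
    expression = expression,
    gene_ids = rownames(expression),
    sample_ids = colnames(expression),
    age = as.numeric(age),
    disease = as.integer(disease),
    batch = as.character(batch %||% rep("b1", n)),
    split = as.character(split %||% rep("train", n)),
    truth = truth
  ), class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf("expression_study: %d genes x %d samples (%d train / %d test; %d diseased)\n",
              nrow(x$expression), ncol(x$expression),
              sum(x$split == "train"), sum(x$split == "test"), sum(x$disease)))
  invisible(x)
}

#' Subset a study by samples and/or genes
#' @param study An `expression_study`.
#' @param samples Logical/integer/character sample selector.
#' @param genes Logical/integer/character gene selector.
#' @return The subset `expression_study`.
#' @export
subset_study <- function(study, samples = NULL, genes = NULL) {
  i <- if (is.null(genes)) seq_len(nrow(study$expression)) else genes
  j <- if (is.null(samples)) seq_len(ncol(study$expression)) else samples
  X <- study$expression[i, j, drop = FALSE]
  jj <- seq_len(ncol(study$expression))
  names(jj) <- colnames(study$expression)
  j_idx <- jj[colnames(X)]
  new_expression_study(X, study$age[j_idx], study$disease[j_idx],
                       study$batch[j_idx], study$split[j_idx], study$truth)
}

#' Write a study to tab-separated files
#'
#' Writes `<prefix>_expression.tsv` (gene_id column then one column per
#' sample, floats at 17 significant digits), `<prefix>_samples.tsv`
#' (sample_id, age, disease, batch, split), and, when truth labels exist,
#' `<prefix>_truth.tsv`.
#'
#' @param study An `expression_study`.
#' @param prefix Output path prefix.
#' @return Invisibly, the vector of files written.
#' @export
write_study <- function(study, prefix) {
  fe <- paste0(prefix, "_expression.tsv")
  fs <- paste0(prefix, "_samples.tsv")
  em <- data.frame(gene_id = study$gene_ids,
                   signif(study$expression, 17), check.names = FALSE)
  colnames(em) <- c("gene_id", study$sample_ids)
  utils::write.table(format(em, digits = 17, trim = TRUE, scientific = FALSE),
                     fe, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = study$sample_ids,
               age = format(study$age, digits = 17, trim = TRUE),
               disease = study$disease, batch = study$batch,
               split = study$split),
    fs, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(fe, fs)
  if (!is.null(study$truth)) {
    ft <- paste0(prefix, "_truth.tsv")
    utils::write.table(study$truth, ft, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <- c(files, ft)
  }
  invisible(files)
}

#' Read a study written by [write_study()]
#'
#' @param prefix Path prefix used when writing.
#' @return An `expression_study`.
#' @export
read_study <- function(prefix) {
  fe <- paste0(prefix, "_expression.tsv")
  fs <- paste0(prefix, "_samples.tsv")
  if (!file.exists(fe) || !file.exists(fs))
    stop("read_study: missing ", fe, " or ", fs)
  em <- utils::read.delim(fe, check.names = FALSE, colClasses = "character")
  if (ncol(em) < 2) stop("parse error in ", fe, ": need gene_id plus sample columns")
  dup <- which(duplicated(em$gene_id))
  if (length(dup))
    stop("parse error in ", fe, " line ", dup[1] + 1L,
         ": duplicated gene id '", em$gene_id[dup[1]], "'")
  X <- as.matrix(em[, -1, drop = FALSE])
  mode(X) <- "numeric"
  if (any(is.na(X))) {
    bad <- which(rowSums(is.na(X)) > 0)[1]
    stop("parse error in ", fe, " line ", bad + 1L, ": non-numeric expression value")
  }
  rownames(X) <- em$gene_id
  sm <- utils::read.delim(fs, stringsAsFactors = FALSE)
  need <- c("sample_id", "age", "disease", "batch", "split")
  if (!all(need %in% colnames(sm)))
    stop("parse error in ", fs, ": missing columns ",
         paste(setdiff(need, colnames(sm)), collapse = ", "))
  if (anyDuplicated(sm$sample_id))
    stop("parse error in ", fs, ": duplicated sample id")
  if (!setequal(sm$sample_id, colnames(X)))
    stop("parse error: sample sheet and expression columns disagree")
  sm <- sm[match(colnames(X), sm$sample_id), ]
  ft <- paste0(prefix, "_truth.tsv")
  truth <- if (file.exists(ft)) utils::read.delim(ft, stringsAsFactors = FALSE) else NULL
  new_expression_study(X, sm$age, sm$disease, sm$batch, sm$split, truth)
}

#' Gene sets derived from planted cohort truth (synthetic GMT material)
#'
#' Builds a small gene-set collection for enrichment tests: one set per
#' planted role plus `n_decoys` random sets of the same size as the
#' inflammation set. Purely synthetic — named so the planted mediation set is
#' recognizable in enrichment output.
#'
#' @param study An `expression_study` with a `truth` table.
#' @param n_decoys Number of random decoy sets.
#' @param seed Seed for the decoy draws.
#' @return Named list of gene-id vectors.
#' @export
truth_gene_sets <- function(study, n_decoys = 5, seed = 1L) {
  if (is.null(study$truth)) stop("study carries no truth labels")
  tr <- study$truth
  sets <- list(
    SYNTH_AGING = tr$gene_id[tr$role == "aging"],
    SYNTH_INFLAMMATORY_MEDIATORS = tr$gene_id[tr$role == "inflammation"],
    ## the inflamm-aging axis: the planted mediators plus their aging
    ## drivers — the set a GO-style inflammatory-response term emulates
    SYNTH_INFLAMM_AGING_AXIS = tr$gene_id[tr$role %in% c("aging", "inflammation")],
    SYNTH_DISEASE_RESPONSE = tr$gene_id[tr$role == "disease"]
  )
  m <- max(3L, length(sets$SYNTH_INFLAMMATORY_MEDIATORS))
  with_seed(seed, {
    for (i in seq_len(n_decoys)) {
      sets[[sprintf("SYNTH_DECOY_%02d", i)]] <-
        sample(tr$gene_id, min(m, nrow(tr)))
    }
  })
  sets
}
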