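## Eight-step preprocessing chain: integrate, zero-fill, zero-gene filter,
## outlier-aware log transform, reference z-score, SVD component removal,
## final reference z-score.

#' Preprocessing parameters
#'
#' @param zero_fraction_threshold Genes with a fraction of exact zeros at or
#'   above this are removed (default 0.30).
#' @param outlier_sd_multiplier A gene is log2(x+1)-transformed when any of
#'   its values lies beyond mean +/- multiplier * sd (default 3).
#' @param n_svd_components Number of reference-derived gene-space singular
#'   components removed from all samples (default 3).
#' @param reference_group Either `"healthy_aged_train"` (default: healthy
#'   samples, age > 50 years, training split) or a logical sample selector.
#' @return A `preprocess_params` list.
#' @export
preprocess_params <- function(zero_fraction_threshold = 0.30,
                              outlier_sd_multiplier = 3,
                              n_svd_components = 3,
                              reference_group = "healthy_aged_train") {
  if (zero_fraction_threshold < 0 || zero_fraction_threshold > 1)
    stop("zero_fraction_threshold must lie in [0,1]")
  if (outlier_sd_multiplier <= 0) stop("outlier_sd_multiplier must be positive")
  if (n_svd_components < 0) stop("n_svd_components must be non-negative")
  structure(list(zero_fraction_threshold = zero_fraction_threshold,
                 outlier_sd_multiplier = outlier_sd_multiplier,
                 n_svd_components = as.integer(n_svd_components),
                 reference_group = reference_group),
            class = "preprocess_params")
}

#' Resolve the reference-sample selector of a study
#' @noRd
reference_samples <- function(study, reference_group) {
  if (is.logical(reference_group)) {
    stopifnot(length(reference_group) == ncol(study$expression))
    return(reference_group)
  }
  if (identical(reference_group, "healthy_aged_train"))
    return(study$disease == 0 & study$age > 50 & study$split == "train")
  if (identical(reference_group, "healthy_aged"))
    return(study$disease == 0 & study$age > 50)
  stop("unknown reference_group selector: ", reference_group)
}

#' Integrate studies over the union of genes, filling absences with zero
#'
#' A gene absent from a study contributes 0 for that study's samples; sample
#' metadata are concatenated. Sample ids must be disjoint across studies.
#'
#' @param studies List of `expression_study` objects (length >= 1).
#' @return A single merged `expression_study`.
#' @export
integrate_and_fill <- function(studies) {
  stopifnot(length(studies) >= 1)
  if (length(studies) == 1) return(studies[[1]])
  all_samples <- unlist(lapply(studies, `[[`, "sample_ids"))
  if (anyDuplicated(all_samples))
    stop("integration error: duplicate sample ids across studies")
  genes <- Reduce(union, lapply(studies, `[[`, "gene_ids"))
  X <- matrix(0, nrow = length(genes), ncol = length(all_samples),
              dimnames = list(genes, all_samples))
  for (s in studies) X[s$gene_ids, s$sample_ids] <- s$expression
  truths <- Filter(Negate(is.null), lapply(studies, `[[`, "truth"))
  truth <- if (length(truths)) unique(do.call(rbind, truths)) else NULL
  new_expression_study(
    X,
    age = unlist(lapply(studies, `[[`, "age")),
    disease = unlist(lapply(studies, `[[`, "disease")),
    batch = unlist(lapply(studies, `[[`, "batch")),
    split = unlist(lapply(studies, `[[`, "split")),
    truth = truth
  )
}

#' Remove genes with too many exact zeros
#'
#' @param study An `expression_study`.
#' @param threshold Genes whose fraction of exact-zero entries is `>=`
#'   threshold are removed; survivor order is preserved.
#' @return The filtered study.
#' @export
filter_zero_genes <- function(study, threshold = 0.30) {
  stopifnot(threshold >= 0, threshold <= 1)
  frac0 <- rowMeans(study$expression == 0)
  keep <- frac0 < threshold
  if (!any(keep)) warning("filter_zero_genes removed every gene")
  subset_study(study, genes = which(keep))
}

#' Log2-transform genes that contain outliers
#'
#' A gene is flagged when any of its values lies beyond mean +/-
#' `multiplier` * sd (sd 0 means never flagged); flagged genes are replaced by
#' log2(value + 1), others are untouched. The flag list is attached as
#' attribute `"log_transformed"`.
#'
#' @param study An `expression_study` with non-negative expression.
#' @param multiplier Outlier SD multiplier (default 3).
#' @return The transformed study.
#' @export
log_transform_outlier_genes <- function(study, multiplier = 3) {
  X <- study$expression
  if (any(X < 0)) {
    g <- rownames(X)[which(rowSums(X < 0) > 0)[1]]
    stop("log_transform_outlier_genes: negative values (gene ", g,
         "); expression must be non-negative at this stage")
  }
  mu <- rowMeans(X)
  sdv <- apply(X, 1, stats::sd)
  lim <- multiplier * sdv
  flagged <- rowSums(abs(X - mu) > lim) > 0 & sdv > 0
  X[flagged, ] <- log2(X[flagged, , drop = FALSE] + 1)
  out <- study
  out$expression <- X
  attr(out, "log_transformed") <- rownames(X)[flagged]
  out
}

#' Z-score all samples against reference-group statistics
#'
#' Every value of gene g becomes (x - mu_g) / sigma_g where mu_g and sigma_g
#' are computed on the reference samples only. Genes constant in the
#' reference are dropped with a warning.
#'
#' @param study An `expression_study`.
#' @param reference_group Selector as in [preprocess_params()].
#' @return The normalized study.
#' @export
reference_zscore <- function(study, reference_group = "healthy_aged_train") {
  ref <- reference_samples(study, reference_group)
  if (!any(ref)) stop("reference_zscore: empty reference group")
  R <- study$expression[, ref, drop = FALSE]
  mu <- rowMeans(R)
  sdv <- apply(R, 1, stats::sd)
  keep <- sdv > 0
  if (!all(keep))
    warning("reference_zscore dropped ", sum(!keep),
            " gene(s) constant in the reference group")
  X <- (study$expression[keep, , drop = FALSE] - mu[keep]) / sdv[keep]
  out <- subset_study(study, genes = which(keep))
  out$expression <- X
  out
}

#' Remove reference-derived SVD components from all samples
#'
#' Left singular vectors (gene-space components) are computed from the
#' reference submatrix; the projection of every sample onto the first
#' `n_components` of them is subtracted.
#'
#' @param study A reference-z-scored `expression_study`.
#' @param n_components Number of components to remove (0 = identity).
#' @param reference_group Selector as in [preprocess_params()].
#' @return The corrected study.
#' @export
svd_component_removal <- function(study, n_components = 3,
                                  reference_group = "healthy_aged_train") {
  if (n_components == 0) return(study)
  ref <- reference_samples(study, reference_group)
  R <- study$expression[, ref, drop = FALSE]
  sv <- svd(R)
  rank <- sum(sv$d > sv$d[1] * 1e-10)
  if (n_components >= rank)
    stop("svd_component_removal: n_components (", n_components,
         ") must be below the reference submatrix rank (", rank, ")")
  U <- sv$u[, seq_len(n_components), drop = FALSE]
  out <- study
  out$expression <- study$expression - U %*% (t(U) %*% study$expression)
  dimnames(out$expression) <- dimnames(study$expression)
  out
}

#' Run the full preprocessing chain
#'
#' Applies, in fixed order: integration with zero fill (when a list of
#' studies is given), zero-gene filtering, outlier-aware log transform,
#' reference z-scoring, SVD component removal, and a final reference
#' z-scoring. This is the only supported entry point for the chain; partial
#' re-application re-estimates reference statistics and is not idempotent.
#'
#' @param study An `expression_study` or a list of them.
#' @param params A [preprocess_params()].
#' @return The preprocessed `expression_study`.
#' @export
preprocess <- function(study, params = preprocess_params()) {
  if (!inherits(study, "expression_study") && is.list(study))
    study <- integrate_and_fill(study)
  study <- filter_zero_genes(study, params$zero_fraction_threshold)
  study <- log_transform_outlier_genes(study, params$outlier_sd_multiplier)
  study <- reference_zscore(study, params$reference_group)
  study <- svd_component_removal(study, params$n_svd_components,
                                 params$reference_group)
  reference_zscore(study, params$reference_group)
}
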