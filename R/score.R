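## kNN-distance inflamm-aging score, age adjustment, and group comparison.

#' Inflamm-aging score of expression profiles
#'
#' Restricted to the marker genes, each sample's score is the summed cosine
#' distance to its `m_neighbors` nearest healthy-young references minus the
#' summed cosine distance to its `m_neighbors` nearest healthy-old
#' references: far from young and close to old means a high, aged-like score.
#'
#' @param X Genes x samples matrix (or a single named vector) to score.
#' @param young_refs,old_refs Genes x samples reference matrices (healthy
#'   young / healthy old training samples).
#' @param markers Marker gene ids present in all three matrices.
#' @param m_neighbors Number of nearest references per pool (default 9).
#' @return Numeric score per sample of `X`.
#' @export
inflamm_aging_score <- function(X, young_refs, old_refs, markers,
                                m_neighbors = 9) {
  if (is.vector(X)) X <- matrix(X, ncol = 1, dimnames = list(names(X), "sample"))
  miss <- setdiff(markers, Reduce(intersect, list(rownames(X), rownames(young_refs),
                                                  rownames(old_refs))))
  if (length(miss)) stop("markers absent from inputs: ", paste(miss, collapse = ", "))
  if (ncol(young_refs) < m_neighbors || ncol(old_refs) < m_neighbors)
    stop("fewer than m_neighbors reference samples in a pool")
  A <- t(X[markers, , drop = FALSE])
  if (any(rowSums(A^2) == 0)) stop("zero-norm marker vector in scored samples")
  Dy <- cosine_distance(A, t(young_refs[markers, , drop = FALSE]))
  Do <- cosine_distance(A, t(old_refs[markers, , drop = FALSE]))
  ## a reference sample never matches itself (leave-one-out by sample id)
  mask_self <- function(D) {
    hit <- intersect(rownames(D), colnames(D))
    if (length(hit)) D[cbind(match(hit, rownames(D)), match(hit, colnames(D)))] <- Inf
    D
  }
  Dy <- mask_self(Dy); Do <- mask_self(Do)
  if (min(rowSums(is.finite(Dy))) < m_neighbors ||
      min(rowSums(is.finite(Do))) < m_neighbors)
    stop("fewer than m_neighbors usable reference samples in a pool")
  sum_m_smallest <- function(D) {
    apply(D, 1, function(d) sum(sort(d, partial = seq_len(m_neighbors))[seq_len(m_neighbors)]))
  }
  stats::setNames(sum_m_smallest(Dy) - sum_m_smallest(Do), colnames(X))
}

#' Score every sample of a study against healthy training references
#'
#' Convenience wrapper building the young/old healthy reference pools from
#' the training split (age threshold 50 years) and scoring all samples. With
#' `kind = "disease"` the pools are instead healthy vs diseased training
#' samples and the markers are disease markers, giving the disease score.
#'
#' @param study Preprocessed `expression_study`.
#' @param markers Marker gene ids.
#' @param kind `"aging"` (young/old pools) or `"disease"` (healthy/diseased
#'   pools).
#' @param m_neighbors Neighbors per pool.
#' @return Numeric score per sample.
#' @export
score_study <- function(study, markers, kind = c("aging", "disease"),
                        m_neighbors = 9) {
  kind <- match.arg(kind)
  tr <- study$split == "train"
  if (kind == "aging") {
    pool_a <- tr & study$disease == 0 & study$age <= 50
    pool_b <- tr & study$disease == 0 & study$age > 50
  } else {
    pool_a <- tr & study$disease == 0
    pool_b <- tr & study$disease == 1
  }
  inflamm_aging_score(study$expression,
                      study$expression[, pool_a, drop = FALSE],
                      study$expression[, pool_b, drop = FALSE],
                      markers, m_neighbors)
}

#' Hyperbolic age transform used for adjustment
#'
#' tanh((age - 50)/50): 0 at age 50, strictly increasing, range (-1, 1).
#' @param age Age(s) in years.
#' @return Transformed age(s).
#' @export
transformed_age_tanh <- function(age) tanh((age - 50) / 50)

#' Age-adjust scores by regression on transformed age
#'
#' Fits raw_score ~ tanh((age-50)/50) by OLS (with intercept) within
#' `fit_group` — healthy samples by default, so disease-driven acceleration
#' is not regressed out — and subtracts b * transformed_age from every
#' sample's raw score (the intercept is discarded).
#'
#' @param raw_score Numeric score per sample.
#' @param age Age per sample (years).
#' @param fit_group Logical selector of the samples used to estimate b
#'   (size >= 3, non-constant transformed age).
#' @return A `score_table` data.frame: sample, raw_score, transformed_age,
#'   adjusted_score, with attribute `"b"`.
#' @export
adjust_by_age <- function(raw_score, age, fit_group = NULL) {
  n <- length(raw_score)
  stopifnot(length(age) == n)
  if (is.null(fit_group)) fit_group <- rep(TRUE, n)
  if (sum(fit_group) < 3) stop("adjust_by_age: fit_group must have >= 3 samples")
  t_age <- transformed_age_tanh(age)
  if (stats::sd(t_age[fit_group]) == 0)
    stop("adjust_by_age: constant transformed age in fit_group")
  fit <- ols_resid(raw_score[fit_group], t_age[fit_group])
  adjusted <- raw_score - fit$b * t_age
  out <- data.frame(
    sample = names(raw_score) %||% as.character(seq_len(n)),
    raw_score = as.numeric(raw_score),
    transformed_age = t_age,
    adjusted_score = adjusted,
    stringsAsFactors = FALSE
  )
  attr(out, "b") <- fit$b
  class(out) <- c("score_table", "data.frame")
  out
}

#' Kruskal-Wallis comparison of scores between groups
#'
#' @param scores Numeric score per sample.
#' @param groups Group label per sample (>= 2 non-empty groups).
#' @return List: `statistic` (H, tie-corrected), `p_value`, `df`, and a
#'   `summary` data.frame of per-group n, mean, and median.
#' @export
compare_groups <- function(scores, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("compare_groups: need at least 2 groups")
  if (any(table(groups) == 0)) stop("compare_groups: empty group")
  kt <- stats::kruskal.test(scores, groups)
  list(
    statistic = unname(kt$statistic),
    p_value = kt$p.value,
    df = unname(kt$parameter),
    summary = data.frame(
      group = levels(groups),
      n = as.vector(table(groups)),
      mean = as.vector(tapply(scores, groups, mean)),
      median = as.vector(tapply(scores, groups, median))
    )
  )
}
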