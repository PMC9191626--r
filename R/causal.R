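## Expression-based Mendelian-randomization filter cascade:
## stratification, instrument-risk ordering, permutation confounder tests,
## correlation/partial-correlation outcome tests, weak-instrument residual
## filter, and horizontal-pleiotropy residual cascade.

#' Parameters of the causal cascade
#'
#' @param n_perm Permutation draws for the confounder tests (default 1000).
#' @param perm_p_max Permutation p threshold (default 0.05).
#' @param kw_p_max,kw_fdr_max Kruskal-Wallis p / BH FDR thresholds of the
#'   residual filters (defaults 0.05 / 0.2).
#' @param residual_d_form `"product"` (residual of the disease marker on the
#'   elementwise product with the aging marker, symmetric with the other
#'   residuals) or `"plain"` (ordinary regression on the aging marker).
#' @param inflammation_threshold Quantile of the healthy scores splitting
#'   inflammation+/- (default 0.5, the median).
#' @param seed Seed for the permutation draws.
#' @return A `causal_params` list.
#' @export
causal_params <- function(n_perm = 1000, perm_p_max = 0.05,
                          kw_p_max = 0.05, kw_fdr_max = 0.2,
                          residual_d_form = c("product", "plain"),
                          inflammation_threshold = 0.5, seed = 1L) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  structure(list(n_perm = as.integer(n_perm), perm_p_max = perm_p_max,
                 kw_p_max = kw_p_max, kw_fdr_max = kw_fdr_max,
                 residual_d_form = match.arg(residual_d_form),
                 inflammation_threshold = inflammation_threshold,
                 seed = as.integer(seed)),
            class = "causal_params")
}

#' Stratify samples by inflammation level and disease status
#'
#' Inflammation+/- is assigned by comparing each sample's inflamm-aging score
#' to a quantile (default the median) of the healthy samples' scores.
#' Healthy-low -> "inf-ath-", healthy-high -> "inf+ath-", diseased-high ->
#' "inf+ath+"; diseased-low samples are excluded (label NA).
#'
#' @param score Inflamm-aging score per sample.
#' @param disease Binary disease label per sample.
#' @param threshold Score threshold; default the `quantile_p` quantile of the
#'   healthy scores.
#' @param quantile_p Quantile used when `threshold` is NULL (default 0.5).
#' @return Factor with levels `inf-ath-`, `inf+ath-`, `inf+ath+` (NA =
#'   excluded), with the threshold attached as attribute `"threshold"`.
#' @export
stratify <- function(score, disease, threshold = NULL, quantile_p = 0.5) {
  stopifnot(length(score) == length(disease))
  if (!any(disease == 0) || !any(disease == 1))
    stop("stratify: both disease states must be present")
  if (is.null(threshold))
    threshold <- stats::quantile(score[disease == 0], quantile_p, names = FALSE)
  high <- score > threshold
  lab <- rep(NA_character_, length(score))
  lab[disease == 0 & !high] <- "inf-ath-"
  lab[disease == 0 & high] <- "inf+ath-"
  lab[disease == 1 & high] <- "inf+ath+"
  part <- factor(lab, levels = c("inf-ath-", "inf+ath-", "inf+ath+"))
  sizes <- table(part)
  if (any(sizes < 3))
    stop("stratify: group(s) with fewer than 3 samples: ",
         paste(names(sizes)[sizes < 3], collapse = ", "))
  attr(part, "threshold") <- threshold
  part
}

#' Per-group correlation of markers with the score
#' @noRd
group_marker_score_cor <- function(X, score, partition) {
  sapply(levels(partition), function(g) {
    idx <- which(partition == g)
    row_cor(X[, idx, drop = FALSE], score[idx])
  })
}

#' Instrument-risk filter (strict betweenness over the three groups)
#'
#' Per group, the Pearson correlation of each aging marker with the
#' inflamm-aging score is computed; a marker is retained iff its correlation
#' in inf-ath- lies strictly between those in inf+ath- and inf+ath+.
#'
#' @param X Genes x samples matrix of aging-marker expression.
#' @param score Inflamm-aging score per sample.
#' @param partition Factor from [stratify()] (NA = excluded samples).
#' @return Data.frame: marker, the three correlations, and `retained`.
#' @export
instrument_risk_filter <- function(X, score, partition) {
  X <- as.matrix(X)
  R <- group_marker_score_cor(X, score, partition)
  degen <- rowSums(is.na(R)) > 0
  if (any(degen))
    message("instrument_risk_filter: skipped ", sum(degen),
            " marker(s) with degenerate variance")
  retained <- !degen & strictly_between(R[, "inf-ath-"], R[, "inf+ath-"],
                                        R[, "inf+ath+"])
  data.frame(marker = rownames(X),
             cor_low = R[, "inf-ath-"], cor_highH = R[, "inf+ath-"],
             cor_dis = R[, "inf+ath+"], retained = retained,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Weak-instrument residual filter statistics
#'
#' The score is regressed (with intercept) on the elementwise product
#' score * marker; the residual is compared between diseased and control
#' samples by Kruskal-Wallis. A strong instrument leaves a residual that
#' still separates the groups.
#'
#' @param marker Aging-marker expression per sample.
#' @param score Inflamm-aging score per sample.
#' @param disease Binary labels per sample.
#' @return List: `b`, `residual`, `kw_p`, `degenerate`.
#' @export
weak_instrument_filter <- function(marker, score, disease) {
  fit <- ols_resid(score, score * marker)
  if (fit$degenerate) {
    warning("weak_instrument_filter: degenerate regressor; marker dropped")
    return(list(b = fit$b, residual = fit$resid, kw_p = 1, degenerate = TRUE))
  }
  p <- stats::kruskal.test(fit$resid, factor(disease))$p.value
  list(b = fit$b, residual = fit$resid, kw_p = p, degenerate = FALSE)
}

#' Horizontal-pleiotropy residual-cascade statistics
#'
#' Builds residual_A (disease marker on its product with the score),
#' residual_B (disease marker on its product with the aging marker),
#' residual_C (residual_A on residual_B), and residual_D (disease marker on
#' the aging marker, in product or plain form), then compares
#' residual_C - residual_D between diseased and control samples by
#' Kruskal-Wallis. Mediated pairs keep a group difference; pleiotropic
#' (direct-path) pairs do not.
#'
#' @param aging,disease_marker Expression vectors per sample.
#' @param score Inflamm-aging score per sample.
#' @param disease Binary labels per sample.
#' @param residual_d_form `"product"` or `"plain"` (see [causal_params()]).
#' @return List with the four residuals, coefficients `b1`..`b4`, `kw_p`,
#'   `degenerate`.
#' @export
pleiotropy_filter <- function(aging, disease_marker, score, disease,
                              residual_d_form = "product") {
  fA <- ols_resid(disease_marker, disease_marker * score)
  fB <- ols_resid(disease_marker, disease_marker * aging)
  fC <- ols_resid(fA$resid, fB$resid)
  fD <- if (identical(residual_d_form, "plain")) {
    ols_resid(disease_marker, aging)
  } else {
    ols_resid(disease_marker, disease_marker * aging)
  }
  degen <- fA$degenerate || fB$degenerate || fC$degenerate || fD$degenerate
  dstat <- fC$resid - fD$resid
  p <- if (degen || stats::sd(dstat) == 0) 1 else
    stats::kruskal.test(dstat, factor(disease))$p.value
  if (degen) warning("pleiotropy_filter: degenerate regressor; pair dropped")
  list(residual_A = fA$resid, residual_B = fB$resid, residual_C = fC$resid,
       residual_D = fD$resid, b1 = fA$b, b2 = fB$b, b3 = fC$b, b4 = fD$b,
       kw_p = p, degenerate = degen)
}

#' Per-group corr and partial-corr matrices for aging x disease pairs
#' @noRd
pair_group_stats <- function(Xa, Xd, score, partition) {
  out <- list()
  for (g in levels(partition)) {
    idx <- which(partition == g)
    A <- t(Xa[, idx, drop = FALSE]); D <- t(Xd[, idx, drop = FALSE])
    s <- score[idx]
    r_ad <- suppressWarnings(stats::cor(A, D))
    r_as <- as.vector(suppressWarnings(stats::cor(A, s)))
    r_ds <- as.vector(suppressWarnings(stats::cor(D, s)))
    den <- sqrt(outer(pmax(1 - r_as^2, 1e-12), pmax(1 - r_ds^2, 1e-12)))
    pc <- (r_ad - outer(r_as, r_ds)) / den
    out[[g]] <- list(corr = r_ad, pcorr = pc)
  }
  out
}

#' Run the full MR-style causal cascade
#'
#' Applies, over the stratified training samples: (1) stratification by
#' inflammation level; (2) instrument-risk strict-betweenness per aging
#' marker; (3) permutation confounder test per aging marker against scores
#' rebuilt from random marker sets; (4) removal of genes in both marker
#' sets; (5) strict betweenness of the per-group corr - pcorr contrast per
#' aging x disease pair; (6) permutation test of that contrast against
#' random gene pairs; (7) weak-instrument residual filter (KW p + BH FDR
#' across aging markers); (8) pleiotropy residual cascade (KW p + BH FDR
#' across pairs). All statistics are computed for every candidate pair and
#' retention is the conjunction of the stage criteria, so the evidence trail
#' is complete and relaxing any threshold can only grow the retained set.
#'
#' @param study Preprocessed `expression_study`.
#' @param score Inflamm-aging score per sample of `study`.
#' @param aging_markers,disease_markers Marker gene-id vectors (instruments
#'   and outcomes).
#' @param inflammatory_markers Marker ids the score was built from (sets the
#'   size of the simulated-score marker draws).
#' @param params A [causal_params()].
#' @return A `causal_pair_set`: data.frame of every tested pair with
#'   per-group corr/pcorr, contrasts, permutation p's, KW p's/FDRs, stage
#'   flags, and `retained`; ranked by the |contrast| statistic. Attributes:
#'   `partition`, `marker_stats`, `params`.
#' @export
run_causal_cascade <- function(study, score, aging_markers, disease_markers,
                               inflammatory_markers,
                               params = causal_params()) {
  tr <- which(study$split == "train")
  sc <- score[tr]
  dis <- study$disease[tr]
  part <- stratify(sc, dis, quantile_p = params$inflammation_threshold)
  keep_s <- !is.na(part)
  Xtr <- study$expression[, tr, drop = FALSE]

  ## step 4 first so every per-marker stat is on the final candidate sets
  overlap <- intersect(aging_markers, disease_markers)
  aging <- setdiff(intersect(aging_markers, rownames(Xtr)), overlap)
  dmk <- setdiff(intersect(disease_markers, rownames(Xtr)), overlap)
  if (!length(aging) || !length(dmk)) {
    warning("run_causal_cascade: empty marker set; returning empty pair set")
    return(empty_pair_set(part, params))
  }

  part_k <- droplevels(part[keep_s])
  sc_k <- sc[keep_s]; dis_k <- dis[keep_s]
  Xk <- Xtr[, keep_s, drop = FALSE]

  ## step 2: instrument-risk betweenness
  inst <- instrument_risk_filter(Xk[aging, , drop = FALSE], sc_k, part_k)

  ## permutation null pool: genes outside the candidate marker sets, so the
  ## simulated markers emulate non-causal genes (falls back to all genes on
  ## very small universes)
  null_pool <- setdiff(rownames(Xtr), c(aging, dmk))
  if (length(null_pool) < 10) null_pool <- rownames(Xtr)
  score_pool <- setdiff(null_pool, inflammatory_markers)
  if (length(score_pool) < 10) score_pool <- null_pool

  ## step 3: permutation confounder test per aging marker
  obs_m <- abs(inst$cor_highH - inst$cor_dis)
  study_tr <- subset_study(study, samples = tr)
  n_mk <- min(max(1L, length(inflammatory_markers)), length(score_pool))
  null_m <- matrix(NA_real_, nrow = length(aging), ncol = params$n_perm)
  with_seed(substream_seed(params$seed, "causal_perm_marker"), {
    for (b in seq_len(params$n_perm)) {
      rnd <- sample(score_pool, n_mk)
      s_sim <- score_study(study_tr, rnd, kind = "aging")[keep_s]
      Rm <- group_marker_score_cor(Xk[aging, , drop = FALSE], s_sim, part_k)
      null_m[, b] <- abs(Rm[, "inf+ath-"] - Rm[, "inf+ath+"])
    }
  })
  perm_p_m <- vapply(seq_along(aging), function(i)
    permutation_pvalue(obs_m[i], null_m[i, ]), numeric(1))

  ## step 5: corr - pcorr contrast betweenness per pair
  gs <- pair_group_stats(Xk[aging, , drop = FALSE], Xk[dmk, , drop = FALSE],
                         sc_k, part_k)
  diffs <- lapply(gs, function(g) g$corr - g$pcorr)
  btw <- strictly_between(diffs[["inf-ath-"]], diffs[["inf+ath-"]],
                          diffs[["inf+ath+"]])
  contrast <- abs(diffs[["inf+ath-"]] - diffs[["inf+ath+"]])

  ## step 6: permutation test of the contrast against random gene pairs
  null_pair <- numeric(params$n_perm)
  with_seed(substream_seed(params$seed, "causal_perm_pair"), {
    for (b in seq_len(params$n_perm)) {
      gp <- sample(null_pool, 2)
      st <- pair_group_stats(Xk[gp[1], , drop = FALSE],
                             Xk[gp[2], , drop = FALSE], sc_k, part_k)
      d1 <- st[["inf+ath-"]]$corr - st[["inf+ath-"]]$pcorr
      d2 <- st[["inf+ath+"]]$corr - st[["inf+ath+"]]$pcorr
      null_pair[b] <- abs(d1 - d2)
    }
  })
  perm_p_pair <- matrix(vapply(as.vector(contrast), function(o)
    permutation_pvalue(o, null_pair), numeric(1)), nrow = length(aging))

  ## step 7: weak-instrument residual filter per aging marker
  weak <- lapply(aging, function(a)
    weak_instrument_filter(Xk[a, ], sc_k, dis_k))
  kw_p_weak <- vapply(weak, `[[`, numeric(1), "kw_p")
  kw_fdr_weak <- stats::p.adjust(kw_p_weak, "BH")

  ## step 8: pleiotropy residual cascade per pair
  kw_p_pleio <- matrix(NA_real_, length(aging), length(dmk))
  for (i in seq_along(aging)) for (j in seq_along(dmk)) {
    kw_p_pleio[i, j] <- suppressWarnings(
      pleiotropy_filter(Xk[aging[i], ], Xk[dmk[j], ], sc_k, dis_k,
                        params$residual_d_form)$kw_p)
  }
  kw_fdr_pleio <- matrix(stats::p.adjust(as.vector(kw_p_pleio), "BH"),
                         nrow = length(aging))

  pairs <- expand.grid(ai = seq_along(aging), dj = seq_along(dmk))
  res <- data.frame(
    aging_marker = aging[pairs$ai],
    disease_marker = dmk[pairs$dj],
    stringsAsFactors = FALSE
  )
  idx <- cbind(pairs$ai, pairs$dj)
  res$corr_low <- gs[["inf-ath-"]]$corr[idx]
  res$corr_highH <- gs[["inf+ath-"]]$corr[idx]
  res$corr_dis <- gs[["inf+ath+"]]$corr[idx]
  res$pcorr_low <- gs[["inf-ath-"]]$pcorr[idx]
  res$pcorr_highH <- gs[["inf+ath-"]]$pcorr[idx]
  res$pcorr_dis <- gs[["inf+ath+"]]$pcorr[idx]
  res$diff <- contrast[idx]
  res$pass_instrument <- inst$retained[pairs$ai]
  res$perm_p_confounder <- perm_p_m[pairs$ai]
  res$pass_outcome_between <- btw[idx]
  res$perm_p_outcome <- perm_p_pair[idx]
  res$kw_p_weak <- kw_p_weak[pairs$ai]
  res$kw_fdr_weak <- kw_fdr_weak[pairs$ai]
  res$kw_p_pleio <- kw_p_pleio[idx]
  res$kw_fdr_pleio <- kw_fdr_pleio[idx]
  res$retained <- res$pass_instrument &
    res$perm_p_confounder < params$perm_p_max &
    res$pass_outcome_between &
    res$perm_p_outcome < params$perm_p_max &
    res$kw_p_weak < params$kw_p_max & res$kw_fdr_weak < params$kw_fdr_max &
    res$kw_p_pleio < params$kw_p_max & res$kw_fdr_pleio < params$kw_fdr_max
  res <- res[order(-res$diff), ]
  rownames(res) <- NULL
  if (!any(res$retained))
    warning("run_causal_cascade: no pair survived the cascade")
  structure(res, class = c("causal_pair_set", "data.frame"),
            partition = part, marker_stats = inst, params = params)
}

#' @noRd
empty_pair_set <- function(part, params) {
  structure(
    data.frame(aging_marker = character(0), disease_marker = character(0),
               diff = numeric(0), retained = logical(0)),
    class = c("causal_pair_set", "data.frame"),
    partition = part, marker_stats = NULL, params = params)
}

#' Retained pairs of a causal (or sensitivity) pair set
#' @param pairs A `causal_pair_set`.
#' @return The retained subset as a plain data.frame.
#' @export
retained_pairs <- function(pairs) {
  as.data.frame(pairs)[pairs$retained, , drop = FALSE]
}
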