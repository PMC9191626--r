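## Metropolis-Hastings sampling from group-conditioned marker distributions
## and the sign-product sensitivity index.

#' Per-group normal priors for marker expression
#'
#' For each stratification group and each marker gene: sample mean and SD
#' (SD floored at 1e-6).
#'
#' @param X Genes x samples matrix.
#' @param partition Factor from [stratify()] over the samples of `X`.
#' @param markers Marker gene ids.
#' @return Named list (one per group) of data.frames gene/mean/sd.
#' @export
fit_group_priors <- function(X, partition, markers) {
  X <- as.matrix(X)
  markers <- intersect(markers, rownames(X))
  out <- list()
  for (g in levels(partition)) {
    idx <- which(partition == g)
    if (length(idx) < 3) stop("fit_group_priors: group ", g, " has < 3 samples")
    M <- X[markers, idx, drop = FALSE]
    out[[g]] <- data.frame(
      gene = markers,
      mean = if (length(markers)) rowMeans(M) else numeric(0),
      sd = if (length(markers)) pmax(apply(M, 1, stats::sd), 1e-6) else numeric(0),
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  out
}

#' Metropolis-Hastings sampler with symmetric Gaussian random-walk proposal
#'
#' Standard MH: a proposal theta* = theta + N(0, proposal_sd) is accepted
#' with probability min(1, exp(log_target(theta*) - log_target(theta)));
#' the symmetric proposal density cancels from the ratio. The chain starts
#' at `init`, the first 10% of the run is discarded as burn-in, and exactly
#' `n_samples` post-burn-in states are returned (states repeat on
#' rejection).
#'
#' @param log_target Function: numeric state -> log target density (up to a
#'   constant).
#' @param init Initial state (must have finite log target).
#' @param proposal_sd Proposal SD, scalar or per-coordinate.
#' @param n_samples Number of post-burn-in states (default 1000).
#' @param seed Seed for the chain.
#' @return Matrix n_samples x length(init) of states, with attribute
#'   `"acceptance_rate"`.
#' @export
mh_sample <- function(log_target, init, proposal_sd, n_samples = 1000,
                      seed = 1L) {
  stopifnot(n_samples >= 1)
  d <- length(init)
  lp <- log_target(init)
  if (!is.finite(lp)) stop("mh_sample: non-finite log target at initialization")
  n_total <- ceiling(n_samples / 0.9)
  burn <- n_total - n_samples
  out <- matrix(NA_real_, n_total, d)
  acc <- 0L
  with_seed(seed, {
    cur <- init
    for (i in seq_len(n_total)) {
      prop <- cur + stats::rnorm(d, 0, proposal_sd)
      lp_prop <- log_target(prop)
      alpha <- if (is.finite(lp_prop)) min(1, exp(lp_prop - lp)) else 0
      if (stats::runif(1) <= alpha) {
        cur <- prop; lp <- lp_prop; acc <- acc + 1L
      }
      out[i, ] <- cur
    }
  })
  res <- out[(burn + 1):n_total, , drop = FALSE]
  colnames(res) <- names(init)
  attr(res, "acceptance_rate") <- acc / n_total
  res
}

#' Sign-product sensitivity index of an aging-disease pair
#'
#' For each group's sampled marker states, freq_g = mean over samples of
#' sign(theta_aging * theta_disease) (sign(0) contributes 0). The pair is
#' sensitive iff freq in inf-ath- lies strictly between the other two
#' groups; diff = |freq(inf+ath-) - freq(inf+ath+)|.
#'
#' @param samples_by_group Named list (the three groups) of sample matrices
#'   from [mh_sample()] with marker-named columns.
#' @param aging_marker,disease_marker Gene ids of the pair.
#' @return List: `freq` (named vector), `diff`, `sensitive`.
#' @export
sensitivity_index <- function(samples_by_group, aging_marker, disease_marker) {
  freq <- vapply(samples_by_group, function(S) {
    if (is.null(S) || nrow(S) == 0) stop("sensitivity_index: empty sample set")
    mean(sign(S[, aging_marker] * S[, disease_marker]))
  }, numeric(1))
  sens <- strictly_between(freq[["inf-ath-"]], freq[["inf+ath-"]],
                           freq[["inf+ath+"]])
  list(freq = freq,
       diff = abs(freq[["inf+ath-"]] - freq[["inf+ath+"]]),
       sensitive = unname(sens))
}

#' Run the MCMC sensitivity analysis over MR-retained pairs
#'
#' For each stratification group, fits per-marker normal priors over the
#' union of aging, inflammatory, and disease markers, and samples marker
#' states by [mh_sample()]. The target combines the prior with Gaussian
#' likelihoods of the candidate state's inflamm-aging and disease scores
#' under the group's empirical score distributions. Every retained causal
#' pair is then scored by [sensitivity_index()].
#'
#' @param study Preprocessed `expression_study`.
#' @param partition Factor from [stratify()] over the training samples.
#' @param pairs Data.frame with `aging_marker`, `disease_marker` columns
#'   (typically [retained_pairs()]).
#' @param markers A `marker_model` (or list with `aging_markers`,
#'   `inflammatory_markers`, `disease_markers`).
#' @param n_samples Post-burn-in samples per group (default 1000).
#' @param m_neighbors Score neighbors (default 9).
#' @param proposal_scale Proposal SD as a multiple of the prior SD; the
#'   default NULL uses 2.4/sqrt(d) (d = number of markers), the standard
#'   random-walk scaling that keeps acceptance in the 20-50% band as
#'   dimension grows.
#' @param seed Seed; per-group chains use derived substreams.
#' @return A `sensitivity_record` data.frame: pair, the three freqs, diff,
#'   sensitive; sensitive pairs first, ranked by diff descending. Attribute
#'   `"acceptance_rates"`.
#' @export
run_sensitivity <- function(study, partition, pairs, markers,
                            n_samples = 1000, m_neighbors = 9,
                            proposal_scale = NULL, seed = 1L) {
  tr <- which(study$split == "train")
  Xtr <- study$expression[, tr, drop = FALSE]
  keep <- !is.na(partition)
  part_k <- droplevels(partition[keep])
  Xk <- Xtr[, keep, drop = FALSE]

  all_markers <- unique(c(markers$aging_markers, markers$inflammatory_markers,
                          markers$disease_markers))
  all_markers <- intersect(all_markers, rownames(Xk))
  priors <- fit_group_priors(Xk, part_k, all_markers)
  if (is.null(proposal_scale))
    proposal_scale <- 2.4 / sqrt(max(1, length(all_markers)))

  ## score machinery: healthy young/old and healthy/diseased reference pools
  study_tr <- subset_study(study, samples = tr)
  ia_markers <- intersect(markers$inflammatory_markers, all_markers)
  d_markers <- intersect(markers$disease_markers, all_markers)
  sc_ia <- score_study(study_tr, ia_markers, "aging", m_neighbors)[keep]
  sc_d <- score_study(study_tr, d_markers, "disease", m_neighbors)[keep]

  tr_flag <- study_tr$split == "train"
  pools <- list(
    young = study_tr$expression[, tr_flag & study_tr$disease == 0 & study_tr$age <= 50, drop = FALSE],
    old = study_tr$expression[, tr_flag & study_tr$disease == 0 & study_tr$age > 50, drop = FALSE],
    healthy = study_tr$expression[, tr_flag & study_tr$disease == 0, drop = FALSE],
    diseased = study_tr$expression[, tr_flag & study_tr$disease == 1, drop = FALSE]
  )

  samples_by_group <- list()
  acc_rates <- numeric(0)
  for (g in levels(part_k)) {
    pr <- priors[[g]]
    mu <- stats::setNames(pr$mean, pr$gene)
    sdv <- stats::setNames(pr$sd, pr$gene)
    ia_mu <- mean(sc_ia[part_k == g]); ia_sd <- max(stats::sd(sc_ia[part_k == g]), 1e-6)
    d_mu <- mean(sc_d[part_k == g]); d_sd <- max(stats::sd(sc_d[part_k == g]), 1e-6)
    log_target <- function(theta) {
      names(theta) <- pr$gene
      s1 <- inflamm_aging_score(theta[ia_markers], pools$young, pools$old,
                                ia_markers, m_neighbors)
      s2 <- inflamm_aging_score(theta[d_markers], pools$healthy, pools$diseased,
                                d_markers, m_neighbors)
      sum(stats::dnorm(theta, mu, sdv, log = TRUE)) +
        stats::dnorm(s1, ia_mu, ia_sd, log = TRUE) +
        stats::dnorm(s2, d_mu, d_sd, log = TRUE)
    }
    S <- mh_sample(log_target, init = mu, proposal_sd = proposal_scale * sdv,
                   n_samples = n_samples,
                   seed = substream_seed(seed, paste0("mh_", g)))
    samples_by_group[[g]] <- S
    acc_rates[g] <- attr(S, "acceptance_rate")
  }

  res <- pairs[, c("aging_marker", "disease_marker"), drop = FALSE]
  res <- res[res$aging_marker %in% all_markers &
               res$disease_marker %in% all_markers, , drop = FALSE]
  stats_list <- lapply(seq_len(nrow(res)), function(i)
    sensitivity_index(samples_by_group, res$aging_marker[i],
                      res$disease_marker[i]))
  res$freq_low <- vapply(stats_list, function(s) s$freq[["inf-ath-"]], numeric(1))
  res$freq_highH <- vapply(stats_list, function(s) s$freq[["inf+ath-"]], numeric(1))
  res$freq_dis <- vapply(stats_list, function(s) s$freq[["inf+ath+"]], numeric(1))
  res$diff <- vapply(stats_list, `[[`, numeric(1), "diff")
  res$sensitive <- vapply(stats_list, `[[`, logical(1), "sensitive")
  res <- res[order(-res$sensitive, -res$diff), ]
  rownames(res) <- NULL
  structure(res, class = c("sensitivity_record", "data.frame"),
            acceptance_rates = acc_rates,
            samples_by_group = samples_by_group)
}
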