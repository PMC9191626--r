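test_that("stratification splits healthy at the median and excludes diseased-low", {
  set.seed(3)
  score <- c(rnorm(100), rnorm(60, 2))   # healthy, diseased-high
  disease <- rep(c(0, 1), c(100, 60))
  part <- stratify(score, disease)
  expect_equal(sum(part == "inf-ath-", na.rm = TRUE), 50)
  expect_equal(sum(part == "inf+ath-", na.rm = TRUE), 50)
  expect_true(all(is.na(part[disease == 1 & score <= attr(part, "threshold")])))
  ## all diseased below the healthy median -> inf+ath+ too small -> error
  expect_error(stratify(c(rnorm(100), rnorm(20, -10)), rep(c(0, 1), c(100, 20))),
               "fewer than 3")
  expect_error(stratify(rnorm(10), rep(0, 10)), "both disease states")
})

test_that("planted cohorts put most diseased samples in inf+ath+", {
  co <- planted_cohort()
  sc <- planted_scores()
  trn <- co$pp$split == "train"
  part <- stratify(sc[trn], co$pp$disease[trn])
  frac <- sum(part[co$pp$disease[trn] == 1] == "inf+ath+", na.rm = TRUE) /
    sum(co$pp$disease[trn] == 1)
  expect_gte(frac, 0.7)
})

test_that("partial correlation matches its closed form and limiting cases", {
  set.seed(17)
  n <- 10000
  z <- rnorm(n)
  ## z independent of x and y: pcorr ~ corr
  x <- rnorm(n); y <- 0.5 * x + rnorm(n)
  expect_equal(partial_corr(x, y, z), cor(x, y), tolerance = 0.05)
  ## chain x -> z -> y: conditioning on z d-separates x and y
  z2 <- x + rnorm(n)
  y2 <- z2 + rnorm(n)
  expect_lt(abs(partial_corr(x, y2, z2)), 0.05)
  expect_error(partial_corr(x, y, y), "collinear")
  expect_error(partial_corr(rep(1, n), y, z), "zero-variance")
})

test_that("add-one permutation p-values behave at the extremes and in small cases", {
  expect_equal(permutation_pvalue(10, rep(1, 1000)), 1 / 1001)
  ## observed at the median of 4 nulls: 2 nulls >= observed -> (1+2)/5
  expect_equal(permutation_pvalue(2.5, c(1, 2, 3, 4)), 3 / 5)
  expect_equal(permutation_pvalue(0, c(1, 2, 3, 4)), 1)
  expect_error(permutation_pvalue(1, numeric(0)), "empty null")
})

test_that("permutation p-values are uniform when the observed value is a null draw", {
  set.seed(23)
  p <- replicate(500, {
    null <- rnorm(199)
    permutation_pvalue(rnorm(1), null)
  })
  ## ties are expected: permutation p-values are discrete
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("the instrument-risk filter applies strict betweenness", {
  ## craft three groups where marker-score correlation is engineered per group
  set.seed(29)
  n <- 400
  part <- factor(rep(c("inf-ath-", "inf+ath-", "inf+ath+"), each = n),
                 levels = c("inf-ath-", "inf+ath-", "inf+ath+"))
  score <- rnorm(3 * n)
  couple <- function(r) r * score + sqrt(1 - r^2) * rnorm(3 * n)
  ## marker A: correlations ~ (0.3, 0.05, 0.6) -> low strictly between
  mA <- numeric(3 * n)
  for (g_r in list(c("inf-ath-", 0.3), c("inf+ath-", 0.05), c("inf+ath+", 0.6))) {
    idx <- part == g_r[1]
    r <- as.numeric(g_r[2])
    mA[idx] <- r * score[idx] + sqrt(1 - r^2) * rnorm(sum(idx))
  }
  ## marker B: correlations ~ (0.6, 0.05, 0.3) -> low is the largest
  mB <- numeric(3 * n)
  for (g_r in list(c("inf-ath-", 0.6), c("inf+ath-", 0.05), c("inf+ath+", 0.3))) {
    idx <- part == g_r[1]
    r <- as.numeric(g_r[2])
    mB[idx] <- r * score[idx] + sqrt(1 - r^2) * rnorm(sum(idx))
  }
  X <- rbind(A = mA, B = mB)
  colnames(X) <- paste0("s", seq_len(3 * n))
  out <- instrument_risk_filter(X, score, part)
  expect_true(out$retained[out$marker == "A"])
  expect_false(out$retained[out$marker == "B"])
})

test_that("planted instruments are enriched among retained markers", {
  co <- planted_cohort()
  sc <- planted_scores()
  trn <- co$pp$split == "train"
  part <- stratify(sc[trn], co$pp$disease[trn])
  keep <- !is.na(part)
  X <- co$pp$expression[, trn][, keep]
  out <- instrument_risk_filter(X[c(co$aging, co$null[1:30]), ],
                                sc[trn][keep], droplevels(part[keep]))
  truthv <- out$marker %in% co$aging
  ft <- fisher.test(table(retained = out$retained, truth = truthv),
                    alternative = "greater")
  expect_gt(ft$estimate, 1)
  expect_lt(ft$p.value, 0.05)
})

test_that("residual filters have exact OLS orthogonality and degenerate handling", {
  set.seed(31)
  n <- 200
  score <- rnorm(n)
  marker <- rnorm(n)
  disease <- rep(c(0, 1), each = n / 2)
  wf <- weak_instrument_filter(marker, score, disease)
  expect_lt(abs(cor(wf$residual, score * marker)), 1e-10)
  ## constant marker 1: regressor equals the score itself -> residual ~ 0
  wf1 <- weak_instrument_filter(rep(1, n), score, disease)
  expect_lt(sd(wf1$residual), 1e-10)
  dmk <- rnorm(n)
  pf <- pleiotropy_filter(marker, dmk, score, disease)
  expect_lt(abs(cor(pf$residual_A, dmk * score)), 1e-10)
  expect_lt(abs(cor(pf$residual_B, dmk * marker)), 1e-10)
  expect_lt(abs(cor(pf$residual_C, pf$residual_B)), 1e-10)
  ## collinear score and aging marker: difference statistic degenerates
  expect_warning(pfc <- pleiotropy_filter(score, score, score, disease),
                 regexp = NA)
  expect_true(is.finite(pfc$kw_p))
})

test_that("mediated pairs pass the pleiotropy filter more often than direct pairs", {
  set.seed(37)
  n <- 400
  disease <- rep(c(0, 1), each = n / 2)
  n_pairs <- 40
  pass <- function(simulate_pair) {
    mean(replicate(n_pairs, {
      pr <- simulate_pair()
      pleiotropy_filter(pr$a, pr$d, pr$score, disease)$kw_p < 0.05
    }))
  }
  ## mediated: aging -> score -> disease marker; disease elevates the score
  ## and the marker through the score (the planted-cohort situation)
  mediated <- function() {
    a <- rnorm(n)
    score <- 0.8 * disease + ifelse(disease == 1, 0.9, 0.3) * a + rnorm(n, 0, 0.5)
    d <- 0.8 * score + rnorm(n, 0, 0.5)
    list(a = a, d = d, score = score)
  }
  ## pleiotropic: the instrument reaches the marker directly, bypassing the
  ## exposure; the marker carries no exposure-mediated disease signal
  direct <- function() {
    a <- rnorm(n)
    score <- 0.8 * disease + rnorm(n, 0, 0.5)
    d <- 0.6 * a + rnorm(n, 0, 0.5)
    list(a = a, d = d, score = score)
  }
  expect_gt(pass(mediated) / max(pass(direct), 1 / n_pairs), 1.5)
})

test_that("the cascade is deterministic and monotone in its thresholds", {
  co <- planted_cohort()
  sc <- planted_scores()
  agt <- c(co$aging[1:10], co$null[1:10])
  out <- co$inflammation[1:10]
  prm <- causal_params(n_perm = 100, seed = 5L)
  a <- run_causal_cascade(co$pp, sc, agt, out, co$inflammation, prm)
  b <- run_causal_cascade(co$pp, sc, agt, out, co$inflammation, prm)
  expect_identical(as.data.frame(a), as.data.frame(b))
  ## relaxing every threshold never removes a retained pair
  relaxed <- causal_params(n_perm = 100, perm_p_max = 0.2, kw_p_max = 0.2,
                           kw_fdr_max = 0.5, seed = 5L)
  r <- run_causal_cascade(co$pp, sc, agt, out, co$inflammation, relaxed)
  key <- function(d) paste(d$aging_marker, d$disease_marker)
  expect_true(all(key(retained_pairs(a)) %in% key(retained_pairs(r))))
})

test_that("the cascade recovers planted mediation pairs with few false positives", {
  co <- planted_cohort()
  sc <- planted_scores()
  set.seed(99)
  agt <- c(co$aging, sample(co$null, 30))
  out <- c(co$inflammation, sample(setdiff(co$null, agt), 20))
  cp <- run_causal_cascade(co$pp, sc, agt, out, co$inflammation,
                           causal_params(n_perm = 300, seed = 2L))
  rp <- retained_pairs(cp)
  truep <- rp$aging_marker %in% co$aging & rp$disease_marker %in% co$inflammation
  expect_gte(mean(truep), 0.5)
  expect_gte(sum(truep) / (length(co$aging) * length(co$inflammation)), 0.5)
  ## the full evidence trail is serialized for every tested pair
  expect_true(all(c("corr_low", "pcorr_dis", "perm_p_confounder", "perm_p_outcome",
                    "kw_p_weak", "kw_fdr_pleio", "diff") %in% colnames(cp)))
  expect_equal(nrow(cp), length(unique(cp$aging_marker)) *
                 length(unique(cp$disease_marker)))
})
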