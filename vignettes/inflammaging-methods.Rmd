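---
title: "Inflamm-aging analysis of atherosclerosis cohorts: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inflamm-aging analysis of atherosclerosis cohorts: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(inflammaging)
```

## The scientific question

Chronic low-grade inflammation rises with age ("inflamm-aging") and is a
suspected causal intermediate between aging and atherosclerosis. Given blood
gene-expression profiles with per-sample age and disease labels, this package
asks three linked questions:

1. Can a transcriptomic *inflamm-aging score* quantify how far along that
   axis an individual is, and do atherosclerosis patients show an
   accelerated pattern beyond what their age explains?
2. Which aging-marker/outcome-marker gene pairs carry evidence that the
   disease association is *mediated by* the inflammatory program, in an
   expression-based analog of Mendelian randomization (aging markers as
   instruments, the score as exposure, inflamm-aging markers as outcomes)?
3. Which genes sit on the network routes between aging and inflamm-aging
   markers in a score-conditioned differential co-expression network, and
   which biological gene sets do those routes point to?

Every stage is exercised end-to-end on synthetic cohorts with planted ground
truth, so the statistical machinery can be validated without any external
download.

## The synthetic cohort generator

`generate_cohort()` emulates a merged multi-platform case/control cohort:
four strata (healthy young/old, diseased young/old, age threshold 50 years,
young ages uniform on [20, 50], old on [51, 85]), a train/test split,
additive per-batch gene offsets, dropout zeros, and linear-scale (log-normal)
intensities, as microarray matrices are distributed.

The planted causal chain is an *immune-homeostasis* model rather than a
plain linear structural model, for reasons established while designing the
cascade tests (below):

* **Biological age.** `bio = (age - 20)/30 + eta`, `eta ~ N(0, 0.6)`:
  individuals of the same chronological age differ substantially in
  biological age, which is what makes marker genes co-vary within an age
  stratum.
* **Aging genes** load linearly on `bio` (default loading `effect_age =
  1.8` log2 units per `bio` unit, residual SD `noise_sd = 1`). Program
  variance comparable to gene noise emulates the tight co-expression of
  real marker panels.
* **Inflammation genes (mediators).** In healthy samples the inflammatory
  program activates only above a biological-age threshold:
  `I = effect_mediation * max(bio_hat - 1, 0) + w`. Below the threshold the
  program is driven by non-aging factors (`w`), i.e. decoupled. In disease
  the level is elevated (a setpoint shift within the score's resolving
  range) and the aging coupling is *inverted* — in patients, circulating
  inflammatory expression is dominated by the disease process and
  immunosenescent exhaustion, so biologically older patients show
  relatively lower marker expression.
* **Disease genes** repeat the same motif one step downstream (hinge on the
  inflammatory program in health; elevated level `effect_direct` plus full
  coupling in disease).
* **Immune-dysregulation channel.** In diseased samples, aging and
  inflammation genes share an additional direct co-regulation latent with
  random per-gene signs. The signs cancel in marker averages (the score is
  untouched) but gene-pair correlations gain a disease-specific component
  that survives conditioning on the score — the structure the sign-flip
  differential-network rule is designed to detect.

Why not a plain linear Gaussian chain with a constant "reduced in health"
mediation weight? Two experiments during design ruled it out. First, the
causal cascade's strict-betweenness filters require the low-inflammation
healthy group's correlations to lie *between* the other two groups; with any
monotone constant-weight coupling, splitting healthy samples at the median
score always makes that group's correlation the smallest of the three
(selection plus attenuation), so true pairs pass at roughly chance. Second,
the kNN cosine-distance score saturates outside the healthy reference
support, so a disease group elevated by a large constant offset loses all
within-group score resolution. The hinge-plus-inversion model produces three
genuinely distinct coupling regimes (correlation ladder roughly 0 / +0.45 /
−0.4 across inf−ath−, inf+ath−, inf+ath+) while keeping every conditional
distribution Gaussian and keeping the *average* healthy mediation weight
well below the disease-side magnitude.

Batch defaults (`n_batches = 4`, `batch_sd = 2.0`) are chosen so that the
top three singular components of the healthy-aged reference are platform
axes, mirroring the situation the preprocessing chain was written for (seven
platforms, three components removed). With fewer or weaker batches the
planted biology axis itself enters the top three and the SVD step removes
the signal it is meant to protect.

What the generator does **not** model: count-based (RNA-seq) noise,
platform-specific probe effects, gene-length or GC biases, and realistic
pathway topology. Passing tests therefore demonstrate that the machinery
recovers the planted structure under the stated assumptions — not that it
would perform equally on any real cohort.

## Preprocessing

`preprocess()` applies, in fixed order: integration over the gene union with
zero fill; removal of genes with ≥ 30% exact zeros; per-gene `log2(x + 1)`
restricted to genes containing outliers beyond mean ± 3 SD (on the linear
scale virtually every gene, which recovers the Gaussian log2 signal);
z-scoring against the healthy-aged *training* samples; subtraction of the
projections onto the top `n_svd_components = 3` gene-space singular vectors
of that reference; and a final reference z-scoring. The chain is exposed as
a single entry point because partial re-application re-estimates reference
statistics and is not idempotent. Using the training split of the
healthy-aged samples (rather than all of them) keeps the test split out of
every fitted statistic.

## Predictors and the marker model

The interaction transform replaces each gene's profile by
`sum_j relevance(i, j) * x_i * x_j` over its top `floor(log2(n + 1))`
partners, partners ranked by `|relevance|` (the Pearson correlation of the
gene product with the phenotype — binary disease labels, or the logistic
age transform `1/(1 + exp(-(age - 50)/50))` for the aging model), ties
broken by gene order. ReliefF (a deterministic all-instances variant with
10 nearest hits/misses on range-scaled features, Manhattan distance) ranks
the transformed features; a cosine-distance kNN (k = 5, majority vote,
distance ties to the smaller index, vote ties to the smaller class) with
stratified 10-fold cross-validation picks the feature count (smallest count
at the maximal accuracy).

`build_improved_model()` integrates the three marker families: inflammatory
candidates are intersected with the study and removed from the aging and
disease candidate lists; candidates are filtered by Kruskal–Wallis
(p < 0.05, BH FDR < 0.2) — aging candidates between old and young samples,
disease candidates between disease and control (the grouping that makes the
aging filter select age-dependent genes; a disease-vs-control grouping there
would discard genuine aging markers, which carry no direct disease shift);
inflamm-aging markers are the inflammatory markers whose interaction
transform restricted to aging-marker partners survives the same filter; and
the disease markers are re-selected by ReliefF + kNN over candidates whose
inflamm-aging-transformed versions replace the originals (top
`min(500, available)`).

## The inflamm-aging score

For marker genes only, each sample's score is the summed cosine distance to
its 9 nearest healthy-young references minus the summed distance to its 9
nearest healthy-old references — far from young and close to old means
aged-like. Reference samples are scored leave-one-out (a reference never
matches itself), which removes the self-match bias that would otherwise
inflate every reference sample's score. The age adjustment fits
`raw ~ tanh((age - 50)/50)` by OLS **within healthy samples only** — fitting
on everyone would regress out exactly the disease acceleration the score is
meant to expose — and subtracts `b * transformed_age` everywhere. The
disease score reuses the same operation with disease markers and
healthy/diseased reference pools.

## The causal cascade

Training samples are stratified at the median healthy score into inf−ath−,
inf+ath−, and inf+ath+ (diseased below the threshold are excluded). The
cascade then applies, with every statistic computed for *every* candidate
pair so that the evidence trail is complete and relaxing any threshold can
only grow the retained set:

1. instrument–risk: per group, `cor(marker, score)`; retained iff the
   inf−ath− value lies strictly between the other two;
2. a permutation confounder test per marker: scores are rebuilt from random
   marker sets of the same size and the observed
   `|r(inf+ath−) − r(inf+ath+)|` contrast is compared to 1000 simulated
   contrasts (add-one p);
3. genes in both marker sets are dropped;
4. instrument–outcome: per group, `corr` and first-order partial
   correlation given the score; the pair is retained iff the
   `corr − pcorr` contrast in inf−ath− lies strictly between the other two,
   plus the analogous permutation test against random gene pairs;
5. the weak-instrument residual filter (Kruskal–Wallis of the residual of
   `score ~ score*marker` between disease and control, p < 0.05 and BH
   FDR < 0.2 across markers);
6. the pleiotropy residual cascade (residuals A–D; Kruskal–Wallis of
   `residual_C − residual_D`, same thresholds across pairs).

Outcome variables are the *inflamm-aging markers* (the inflammatory-family
genes), matching both the stated instrument/exposure/outcome roles and the
downstream shortest-path analysis between aging and inflamm-aging markers.
All regressions are slope-with-intercept OLS: intercepts absorb the
z-score offsets that the slope-only written forms ignore.

Both permutation nulls draw simulated markers from genes *outside* the
candidate marker sets (and outside the score's own markers when simulating
scores). On a transcriptome this is what "randomly selected" achieves
implicitly; on a 200-gene cohort where nearly half the genes carry planted
signal, unrestricted draws contaminate the null with true structure and
invert the test.

The `residual_D` form mirrors the elementwise-product regressions of the
other residuals by default (`residual_d_form = "product"`); the plain
regression of the disease marker on the aging marker is available as
`"plain"`.

## The differential network

For every unordered gene pair over the model's marker space, within-group
Pearson correlations and score-conditioned partial correlations are
computed for the disease and control groups, with BH-adjusted p-values. An
edge is kept when the group differences of the two quantities have opposite
signs (sign 0 never passes) and the coefficient tests are significant
(p < 0.05, FDR < 0.1). The statistical filter applies to the *within-group
coefficient* tests by default: under pure mediation the partial-correlation
difference is a fixed positive fraction of the correlation difference with
the same sign, so demanding significant opposite-signed *differences* would
exclude mediated structure by construction; Fisher z-tests of the
differences remain available via `edge_test = "difference"`. The network is
restricted to the marker space because that is the hypothesis space of the
fitted predictor, and because the pairwise FDR burden of an all-gene network
at this scale would swamp the planted signal.

Scale-freeness is checked as the Pearson correlation of log10 degree vs
log10 degree-frequency; the train network is validated against the test
network by a one-sided Fisher's exact test on edge overlap. Shortest paths
between retained pair endpoints use unit edge weights; among equal-length
paths the lexicographically smallest node sequence is returned (a greedy
walk to the smallest-id neighbor that still lies on a shortest path), which
makes every downstream statistic reproducible.

## MCMC sensitivity analysis

Per stratification group, marker states are sampled by random-walk
Metropolis–Hastings: independent normal priors per marker (group sample
mean/SD, SD floored at 1e-6) times Gaussian likelihoods of the candidate
state's inflamm-aging and disease scores under the group's empirical score
distributions. The acceptance ratio is the standard
`min(1, target ratio)` — the symmetric Gaussian proposal cancels (the
printed form with the same transition kernel in numerator and denominator
is treated as a typo). The proposal SD defaults to `2.4/sqrt(d)` times the
prior SD (d = number of markers), the standard scaling that holds
acceptance in the 20–50% band as dimension grows; a fixed multiple would
drive acceptance to zero beyond a few dozen markers. The first 10% of the
run is burn-in; exactly `n_samples` post-burn-in states are returned, with
states repeated on rejection.

Per pair and group, `freq = mean(sign(theta_aging * theta_outcome))`
(normalized by the sample count so groups are comparable; `sign(0)`
contributes 0); a pair is *sensitive* when the inf−ath− frequency lies
strictly between the other two, and pairs are ranked by
`|freq(inf+ath−) − freq(inf+ath+)|`.

## Enrichment and network markers

Every (path, term) combination is tested by the hypergeometric upper tail
`P(X >= k)` with N = all genes surviving preprocessing, M = term size within
that universe, n = path gene count, k = overlap (`stats::phyper`; an
exhaustive-enumeration oracle covers it in the tests). The BH family is
**per path** by default — each path's p-values over the term collection are
controlled together, with the pooled family available via
`bh_family = "pooled"`. A term's score is the sum of `(1 − FDR)` over its
qualifying paths (p < 0.05, FDR < 0.1), and terms are ranked by
qualifying-path count, then score.

A scale caveat that shapes the demonstrations in this package: with a
200-gene universe and a 70-gene planted mediation axis, a 2–4-node path
fully inside the axis has p ≥ 0.014 and can never clear the thresholds — the
test is only informative when sets are a small fraction of the universe (the
motivating study had ~11,300 genes against sets of a few hundred). The
enrichment demonstrations therefore run on a 1000-gene cohort with the same
planted marker counts (universe-to-set ratio 14:1); the 200-gene default is
kept everywhere else.

Network markers are genes counted over the retained pairs' shortest paths as
*interior* nodes (endpoints accrue nothing), ranked by this path-set
betweenness. The permutation null redraws the same number of random node
pairs 1000 times and recomputes the tally; `perm_p` uses the add-one rule,
so it is never exactly zero. Hub genes that sit on many random routes are
correctly non-significant: the null includes the topology.

## Numerical and design choices

* One global seed derives per-stage substreams (a small hash of the stage
  name), so toggling stages never shifts another stage's randomness, and any
  stage rerun from its inputs is bit-for-bit reproducible.
* Cosine similarity of a zero-norm vector is defined as 0 (distance 1);
  zero-variance genes are dropped (reference scaling) or skipped with a
  message (group statistics); `sign(0)` never satisfies the sign-flip rule.
* Correlations are clamped to ±(1 − 1e−12) before Fisher z-transforms.
* Strict betweenness means strict inequalities; ties reject.
* Problem sizes used throughout the tests and the acceptance analysis: the
  default cohort (200 genes, 348 samples), 1000-gene cohorts for the
  enrichment demonstrations, 1000 permutations for the cascade and marker
  nulls, 1000 post-burn-in MH states per group (50,000/100,000 for the
  sampler-correctness checks).

## Known limitations

The generator's immune-homeostasis regimes are one mechanism that produces
the three-group coupling ladder the cascade detects; other mechanisms
(e.g., time-varying couplings, nonlinear saturation) would change the
filters' operating characteristics. The kNN-distance score is bounded by its
reference support and should not be read as a calibrated biological-age
scale. The betweenness permutation keeps the network fixed and redraws
endpoints only; it tests route-specificity, not network uncertainty.
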