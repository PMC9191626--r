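mk_study <- function(X, age = NULL, disease = NULL, split = NULL) {
  n <- ncol(X)
  new_expression_study(X, age %||% rep(60, n), disease %||% rep(0, n),
                       split = split %||% rep("train", n))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("integration takes the gene union and zero-fills absences", {
  Xa <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("a1", "a2")))
  Xb <- matrix(5:10, 2, dimnames = list(c("g2", "g3"), c("b1", "b2", "b3")))
  merged <- integrate_and_fill(list(mk_study(Xa), mk_study(Xb)))
  expect_equal(dim(merged$expression), c(3L, 5L))
  expect_equal(merged$expression["g1", c("b1", "b2", "b3")],
               c(b1 = 0, b2 = 0, b3 = 0))
  expect_equal(merged$expression["g3", c("a1", "a2")], c(a1 = 0, a2 = 0))
  expect_equal(merged$expression["g2", "a1"], 2)
  ## disjoint gene sets -> block structure with zeros off-block
  Xc <- matrix(1, 1, 2, dimnames = list("g9", c("c1", "c2")))
  m2 <- integrate_and_fill(list(mk_study(Xa), mk_study(Xc)))
  expect_equal(sum(m2$expression["g9", c("a1", "a2")]), 0)
  ## single study is returned unchanged
  expect_identical(integrate_and_fill(list(mk_study(Xa))), mk_study(Xa))
  ## duplicated sample ids across studies
  expect_error(integrate_and_fill(list(mk_study(Xa), mk_study(Xa))),
               "duplicate sample ids")
})

test_that("zero-gene filtering removes genes at or above the threshold", {
  X <- rbind(g1 = c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10),
             g2 = c(0, 2, 3, 4, 5, 6, 7, 8, 9, 10),
             g3 = c(0, 0, 0, 4, 5, 6, 7, 8, 9, 10),
             g4 = 1:10)
  colnames(X) <- sprintf("s%d", 1:10)
  out <- filter_zero_genes(mk_study(X), 0.30)
  expect_setequal(rownames(out$expression), c("g1", "g2", "g4"))
  expect_equal(rownames(out$expression), c("g1", "g2", "g4"))  # order kept
  ## threshold 0 removes everything (fraction >= 0 always)
  expect_warning(out0 <- filter_zero_genes(mk_study(X), 0), "every gene")
  expect_equal(nrow(out0$expression), 0L)
  ## no zeros -> identity
  Xn <- X[c("g1", "g4"), ]
  expect_equal(filter_zero_genes(mk_study(Xn), 0.3)$expression, Xn)
})

test_that("only outlier-containing genes are log2-transformed", {
  X <- rbind(gout = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 100),
             gflat = rep(2, 10),
             gok = seq(1, 2, length.out = 10))
  colnames(X) <- sprintf("s%d", 1:10)
  ## hand check: gout has mean 10.9, sd ~31.3 -> 100 > mean + 3sd is FALSE
  ## with sd that large; use multiplier where it flags: |100 - 10.9| = 89.1,
  ## 3 * sd(gout) = 93.9 -> not flagged at 3, flagged at 2.8
  expect_true(abs(100 - mean(X["gout", ])) < 3 * sd(X["gout", ]))
  out3 <- log_transform_outlier_genes(mk_study(X), 3)
  expect_equal(out3$expression, X)  # nothing beyond 3 sd in any gene
  out28 <- log_transform_outlier_genes(mk_study(X), 2.8)
  expect_equal(out28$expression["gout", ], log2(X["gout", ] + 1))
  expect_equal(out28$expression["gok", ], X["gok", ])
  expect_equal(attr(out28, "log_transformed"), "gout")
  ## constant gene: sd 0, never flagged
  expect_equal(out28$expression["gflat", ], X["gflat", ])
  ## negative values refuse with the gene named
  Xneg <- X; Xneg["gok", 1] <- -1
  expect_error(log_transform_outlier_genes(mk_study(Xneg)), "gok")
})

test_that("reference z-scoring uses reference-group statistics only", {
  X <- rbind(g1 = c(0, 4, 6), g2 = c(1, 3, 5))
  colnames(X) <- c("r1", "r2", "d1")
  st <- mk_study(X, age = c(60, 70, 65), disease = c(0, 0, 1))
  out <- reference_zscore(st, st$disease == 0)
  ## g1 reference mean 2, sd 2*sqrt(2)... hand: mean(0,4)=2, sd=2.828
  expect_equal(out$expression["g1", "d1"], (6 - 2) / sd(c(0, 4)))
  ## reference columns themselves have mean 0, sd 1 per gene
  expect_equal(rowMeans(out$expression[, 1:2]), c(g1 = 0, g2 = 0))
  expect_equal(apply(out$expression[, 1:2], 1, sd), c(g1 = 1, g2 = 1))
  ## a disease value of 6 with reference mean 2, sd 2 maps to 2.0
  X2 <- rbind(gA = c(0, 2, 4, 6))
  colnames(X2) <- c("r1", "r2", "r3", "d1")
  st2 <- mk_study(X2, disease = c(0, 0, 0, 1))
  out2 <- reference_zscore(st2, st2$disease == 0)
  expect_equal(out2$expression["gA", "d1"], (6 - 2) / 2)
  ## gene constant in the reference is dropped with a warning
  X3 <- rbind(gA = c(1, 1, 5), gB = c(1, 2, 3))
  colnames(X3) <- c("r1", "r2", "d1")
  st3 <- mk_study(X3, disease = c(0, 0, 1))
  expect_warning(out3 <- reference_zscore(st3, st3$disease == 0), "constant")
  expect_equal(rownames(out3$expression), "gB")
})

test_that("SVD component removal strips a planted batch axis", {
  expect_identical(svd_component_removal(tiny_study(), 0), tiny_study())
  ## rank-1 planted batch offset shared by all samples, n = 1 -> between-
  ## batch variance of gene means drops by >= 90%
  set.seed(9)
  n_g <- 60; n_s <- 40
  X <- matrix(rnorm(n_g * n_s), n_g,
              dimnames = list(sprintf("g%02d", 1:n_g), sprintf("s%02d", 1:n_s)))
  batch <- rep(c(0, 1), each = n_s / 2)
  offset <- rnorm(n_g, 0, 2)
  X <- X + offset %o% batch
  st <- new_expression_study(X, age = rep(60, n_s), disease = rep(0, n_s),
                             batch = paste0("b", batch), split = rep("train", n_s))
  st <- reference_zscore(st, rep(TRUE, n_s))
  batch_var <- function(E) {
    mu <- colMeans(E)
    var(tapply(mu, batch, mean))
  }
  before <- batch_var(st$expression)
  after <- batch_var(svd_component_removal(st, 1, rep(TRUE, n_s))$expression)
  expect_lt(after, 0.1 * before)
  ## removing at least the full rank errors
  expect_error(svd_component_removal(st, n_s, rep(TRUE, n_s)), "rank")
})

test_that("full-rank reference removal leaves a ~zero reference residual", {
  set.seed(4)
  U <- matrix(rnorm(30), 10, 3)
  V <- matrix(rnorm(24), 8, 3)
  X <- U %*% t(V)  # exact rank 3
  dimnames(X) <- list(sprintf("g%02d", 1:10), sprintf("s%02d", 1:8))
  st <- new_expression_study(X, rep(60, 8), rep(0, 8), split = rep("train", 8))
  out <- svd_component_removal(st, 2, rep(TRUE, 8))
  ## rank is 3; removing 3 errors (n_components must stay below rank)
  expect_error(svd_component_removal(st, 3, rep(TRUE, 8)), "rank")
  ## removing 2 leaves a rank-1 residual: Frobenius norm equals sigma_3
  expect_equal(norm(out$expression, "F"), svd(X)$d[3], tolerance = 1e-8)
})

test_that("the preprocessing chain never increases the gene count", {
  co <- planted_cohort()
  expect_lte(nrow(co$pp$expression), nrow(co$raw$expression))
  expect_true(all(rownames(co$pp$expression) %in% rownames(co$raw$expression)))
})
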