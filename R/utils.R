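#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Derive a per-stage RNG substream seed from a global seed
#'
#' Deterministic, stage-order independent, and always below 2^31.
#' @noRd
substream_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (b in utf8ToInt(stage)) h <- (h * 131 + b) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483629 + 1)
}

#' FNV-1a style hash of an R object (for output provenance headers)
#' @noRd
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Pearson correlation of each matrix row with a vector
#'
#' Rows with zero variance (or a zero-variance `y`) get NA.
#' @noRd
row_cor <- function(X, y) {
  X <- as.matrix(X)
  n <- ncol(X)
  stopifnot(length(y) == n)
  xc <- X - rowMeans(X)
  yc <- y - mean(y)
  sx <- sqrt(rowSums(xc^2))
  sy <- sqrt(sum(yc^2))
  r <- as.vector(xc %*% yc) / (sx * sy)
  r[sx == 0 | sy == 0] <- NA_real_
  r
}

#' Cosine distance between rows of A and rows of B
#'
#' Zero-norm rows yield distance 1 (similarity treated as 0).
#' @noRd
cosine_distance <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
  sim <- (A %*% t(B)) / outer(na, nb)
  sim[!is.finite(sim)] <- 0
  d <- 1 - sim
  dimnames(d) <- list(rownames(A), rownames(B))
  d
}

#' First-order Pearson partial correlation
#'
#' Correlation of `x` and `y` with the linear effect of `z` removed:
#' (r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2)).
#'
#' @param x,y,z Numeric vectors of equal length (>= 4).
#' @return A single correlation in \[-1, 1\].
#' @export
partial_corr <- function(x, y, z) {
  stopifnot(length(x) == length(y), length(y) == length(z))
  if (length(x) < 4) stop("partial_corr needs at least 4 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0 || stats::sd(z) == 0)
    stop("partial_corr: zero-variance input")
  rxy <- stats::cor(x, y); rxz <- stats::cor(x, z); ryz <- stats::cor(y, z)
  if (abs(rxz) >= 1 - 1e-12 || abs(ryz) >= 1 - 1e-12)
    stop("partial_corr undefined: conditioning variable collinear with an argument")
  (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
}

#' Add-one permutation p-value
#'
#' p = (1 + #\{null >= observed\}) / (1 + n_perm); never exactly zero.
#'
#' @param observed Observed statistic (scalar).
#' @param null_stats Numeric vector of null statistics.
#' @return p-value in (0, 1\].
#' @export
permutation_pvalue <- function(observed, null_stats) {
  null_stats <- null_stats[is.finite(null_stats)]
  if (length(null_stats) < 1) stop("permutation_pvalue: empty null")
  (1 + sum(null_stats >= observed)) / (1 + length(null_stats))
}

#' OLS slope (with intercept) and residuals of y on x
#' @noRd
ols_resid <- function(y, x) {
  xc <- x - mean(x)
  den <- sum(xc^2)
  if (den < 1e-300) return(list(b = 0, resid = y - mean(y), degenerate = TRUE))
  b <- sum(xc * (y - mean(y))) / den
  a <- mean(y) - b * mean(x)
  list(b = b, resid = y - (a + b * x), degenerate = FALSE)
}

#' Strict betweenness: is a strictly between b and c?
#' @noRd
strictly_between <- function(a, b, c) {
  (a > pmin(b, c)) & (a < pmax(b, c))
}
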