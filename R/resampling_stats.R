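# Resampling statistics: bootstrap percentile CIs over indel regions,
# Spearman rank correlation, Fisher's exact test.

# run code under a temporary RNG state seeded with `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Percentile bootstrap confidence interval over resampling units
#'
#' Resamples whole units (rows for a matrix, elements for a vector) with
#' replacement and returns the percentile 2.5/97.5 interval of the
#' statistic.  The resampling unit in this package is the indel region,
#' never the individual site.
#'
#' @param x Numeric vector (one value per unit) or matrix (one row per
#'   unit); the statistic receives the resampled object.
#' @param B Number of bootstrap trials (default 1000).
#' @param seed Mandatory RNG seed; identical seeds give identical CIs.
#' @param statistic Function mapping the resampled `x` to a scalar
#'   (default: mean of the values / grand mean of the matrix rowsums'
#'   contributions via `mean`).
#' @param conf Confidence level (default 0.95).
#' @return List with `point`, `lo`, `hi`, `B`; `NA` sentinels when fewer
#'   than 2 units are supplied.
#' @export
bootstrap_ci <- function(x, B = 1000L, seed, statistic = mean, conf = 0.95) {
  is_mat <- is.matrix(x)
  n <- if (is_mat) nrow(x) else length(x)
  point <- statistic(x)
  if (n < 2L) {
    return(list(point = point, lo = NA_real_, hi = NA_real_, B = B))
  }
  stats <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      statistic(if (is_mat) x[idx, , drop = FALSE] else x[idx])
    }, numeric(1))
  })
  a <- (1 - conf) / 2
  qs <- stats::quantile(stats, c(a, 1 - a), names = FALSE, type = 7)
  list(point = point, lo = qs[1L], hi = qs[2L], B = B)
}

# all permutations of 1..n as an (n!) x n matrix
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(sub) + seq_len(nrow(sub))
    rest <- seq_len(n)[-i]
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rank correlation with average ranks for ties.  The two-sided p-value is
#' computed by exhaustive permutation enumeration for vectors of length 8
#' or less, and by the t-approximation otherwise.
#'
#' @param x,y Paired numeric vectors, length >= 3.
#' @param exact_max Maximum length for exact enumeration (default 8).
#' @return List with `rho`, `p`, `method`; `NA` sentinels when either
#'   vector has zero variance.
#' @export
spearman <- function(x, y, exact_max = 8L) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(list(rho = NA_real_, p = NA_real_, method = "degenerate"))
  }
  rho <- stats::cor(rx, ry)
  if (n <= exact_max) {
    perms <- all_permutations(n)
    rxc <- rx - mean(rx)
    ryc <- ry - mean(ry)
    # rho is monotone in sum(rxc * ry_perm); compute all at once
    sums <- perms_apply_sums(perms, ryc, rxc)
    denom <- sqrt(sum(rxc^2) * sum(ryc^2))
    rhos <- sums / denom
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
    list(rho = rho, p = p, method = "exact-permutation")
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    list(rho = rho, p = min(1, p), method = "t-approximation")
  }
}

# sum over columns of rxc * ryc[perm] for every permutation (rows)
perms_apply_sums <- function(perms, ryc, rxc) {
  m <- matrix(ryc[perms], nrow(perms), ncol(perms))
  as.numeric(m %*% rxc)
}

#' Fisher's exact test for a 2x2 table
#'
#' Sample odds ratio `(a*d)/(b*c)` and two-sided p-value by the
#' minimum-likelihood rule: the sum of hypergeometric probabilities, over
#' all tables with the observed margins, that do not exceed the observed
#' table's probability.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return List with `odds_ratio` (`Inf` when `b*c = 0` with `a*d > 0`;
#'   `NA` when a margin is zero) and `p` (`1` when a margin is zero).
#' @export
fisher_exact <- function(tab) {
  stopifnot(is.matrix(tab), all(dim(tab) == 2L), all(tab >= 0))
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c
  if (r1 == 0 || r2 == 0 || c1 == 0 || (b + d) == 0) {
    return(list(odds_ratio = NA_real_, p = 1))
  }
  or <- if (b * c == 0) Inf else (a * d) / (b * c)
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(odds_ratio = or, p = min(1, p))
}
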