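# Population-genetic summaries of polymorphic indels: derived-allele
# site-frequency spectrum, neutral infinite-sites expectation, Tajima's D.

#' Derived-allele site-frequency spectrum of polymorphic indels
#'
#' Tallies polarized derived counts into the unfolded spectrum over
#' `i = 1..n-1` and reports the mean derived-allele frequency
#' (`derived_count / n_called`, records weighted equally).  Records with
#' more than half the panel uncalled are excluded.
#'
#' @param table An [indel_polymorphism_table()].
#' @param n Sample size (number of lines); default the table's
#'   `sample_size` attribute.
#' @param type Optional filter: `"insertion"` or `"deletion"`.
#' @return Object of class `sfs`: list with `n`, `counts` (length `n-1`),
#'   `mean_freq`, `n_records`, `type`; `NA` sentinels when no records
#'   survive.
#' @export
indel_sfs <- function(table, n = attr(table, "sample_size"), type = NULL) {
  df <- as.data.frame(table)
  if (!is.null(type)) df <- df[df$type == type, , drop = FALSE]
  df <- df[passes_missingness(df$n_called, n), , drop = FALSE]
  counts <- integer(n - 1L)
  if (nrow(df) == 0L) {
    return(structure(list(n = n, counts = counts, mean_freq = NA_real_,
                          n_records = 0L, type = type), class = "sfs"))
  }
  i <- df$derived_count
  i <- i[i >= 1L & i <= n - 1L]
  tab <- table(factor(i, levels = seq_len(n - 1L)))
  counts <- as.integer(tab)
  mean_freq <- mean(df$derived_count / df$n_called)
  structure(list(n = n, counts = counts, mean_freq = mean_freq,
                 n_records = nrow(df), type = type), class = "sfs")
}

#' Neutral infinite-sites expectation for the derived-allele spectrum
#'
#' Under the neutral infinite-sites model the expected time a derived
#' allele spends at frequency `x` is proportional to `1/x`; in a sample of
#' `n` sequences the expected number of variants at derived count `i` is
#' proportional to `1/i`.  The mean derived-allele frequency is therefore
#' `((n-1)/n) / H(n-1)` with `H` the harmonic number — about 0.175 at
#' `n = 162`.
#'
#' @param n Sample size, at least 2.
#' @return List with `n`, `probs` (normalized expected spectrum over
#'   `i = 1..n-1`) and `mean_freq`.
#' @export
#' @examples
#' neutral_expected_sfs(162)$mean_freq
neutral_expected_sfs <- function(n) {
  if (n < 2L) stop("sample size must be at least 2")
  i <- seq_len(n - 1L)
  H <- sum(1 / i)
  list(n = n, probs = (1 / i) / H, mean_freq = ((n - 1) / n) / H)
}

#' Tajima's D from an unfolded site-frequency spectrum
#'
#' Computes the mean pairwise diversity `pi` and Watterson's estimator
#' from the spectrum and normalizes their difference by the standard
#' variance estimate.  Negative values indicate an excess of rare
#' variants relative to the neutral equilibrium expectation.
#'
#' @param sfs An [indel_sfs()] result, or a list with `n` and `counts`
#'   (counts of variants at derived count `i = 1..n-1`).
#' @return Tajima's D, or `NA_real_` with zero segregating variants.
#' @export
tajimas_d <- function(sfs) {
  n <- sfs$n
  xi <- sfs$counts
  stopifnot(n >= 2L, length(xi) == n - 1L)
  S <- sum(xi)
  if (S == 0L) return(NA_real_)
  i <- seq_len(n - 1L)
  pi <- sum(xi * i * (n - i)) / choose(n, 2)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * S + e2 * S * (S - 1))
  num <- pi - S / a1
  # at n = 2 the variance estimate degenerates to 0 while pi = theta_W
  if (denom == 0) return(if (num == 0) 0 else NA_real_)
  num / denom
}

#' Binned SFS report in frequency intervals
#'
#' Observed derived-allele frequencies (`derived_count / n_called`) and the
#' neutral expectation, binned in intervals of width `width` — the
#' granularity used for the allele-frequency histograms.
#'
#' @param table An [indel_polymorphism_table()].
#' @param n Sample size; default the table's attribute.
#' @param width Frequency bin width (default 0.05).
#' @param type Optional filter: `"insertion"` or `"deletion"`.
#' @return Data frame with `freq_lo`, `freq_hi`, `observed` (proportion of
#'   records) and `expected_neutral`.
#' @export
sfs_binned <- function(table, n = attr(table, "sample_size"),
                       width = 0.05, type = NULL) {
  df <- as.data.frame(table)
  if (!is.null(type)) df <- df[df$type == type, , drop = FALSE]
  df <- df[passes_missingness(df$n_called, n), , drop = FALSE]
  breaks <- seq(0, 1, by = width)
  freq <- df$derived_count / df$n_called
  obs <- table(cut(freq, breaks, right = TRUE, include.lowest = FALSE))
  ne <- neutral_expected_sfs(n)
  efreq <- seq_len(n - 1L) / n
  expd <- tapply(ne$probs, cut(efreq, breaks, right = TRUE,
                               include.lowest = FALSE), sum)
  expd[is.na(expd)] <- 0
  data.frame(
    freq_lo = utils::head(breaks, -1L),
    freq_hi = breaks[-1L],
    observed = if (nrow(df)) as.numeric(obs) / nrow(df) else rep(0, length(obs)),
    expected_neutral = as.numeric(expd))
}
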