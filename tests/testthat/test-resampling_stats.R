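test_that("bootstrap CI collapses for constant data and is deterministic", {
  x <- rep(3.5, 10)
  ci <- bootstrap_ci(x, B = 100L, seed = 1L)
  expect_equal(ci$lo, 3.5)
  expect_equal(ci$hi, 3.5)

  y <- c(1, 4, 2, 8, 5, 7, 3)
  a <- bootstrap_ci(y, B = 500L, seed = 11L)
  b <- bootstrap_ci(y, B = 500L, seed = 11L)
  expect_identical(a, b)
  # percentile CI of the mean contains the point estimate
  expect_true(a$lo <= a$point && a$point <= a$hi)

  # fewer than two units: sentinel
  expect_true(is.na(bootstrap_ci(c(1), B = 10L, seed = 1L)$lo))
})

test_that("bootstrap resamples rows of a matrix as whole units", {
  m <- cbind(c(1, 1, 1, 1), c(2, 4, 6, 8))
  ci <- bootstrap_ci(m, B = 200L, seed = 3L,
                     statistic = function(x) mean(x[, 2] / x[, 1]))
  expect_equal(ci$point, 5)
  expect_true(ci$lo >= 2 && ci$hi <= 8)
})

test_that("spearman handles monotone and degenerate inputs", {
  expect_equal(spearman(1:5, c(2, 5, 9, 11, 30))$rho, 1)
  expect_equal(spearman(1:5, c(30, 11, 9, 5, 2))$rho, -1)
  expect_true(is.na(spearman(1:5, rep(1, 5))$rho))
})

test_that("spearman exact p matches permutation enumeration with ties", {
  skip_if_not_installed("e1071")
  set.seed(7)
  for (rep in 1:5) {
    x <- sample(1:4, 6, replace = TRUE)   # ties likely
    y <- sample(1:4, 6, replace = TRUE)
    if (stats::sd(x) == 0 || stats::sd(y) == 0) next
    got <- spearman(x, y)
    expect_equal(got$method, "exact-permutation")
    expect_equal(got$p, oracle_spearman_p(x, y))
    expect_equal(got$rho, stats::cor(x, y, method = "spearman"))
  }
})

test_that("spearman is invariant under strictly monotone transforms", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.9, 10)
  y <- c(2, 7, 1, 8, 2.8, 1.8, 2.85, 4, 6)
  base <- spearman(x, y)
  tr <- spearman(exp(x), y^3 + 5)
  expect_equal(base$rho, tr$rho)
  expect_equal(base$p, tr$p)
})

test_that("fisher p matches hypergeometric enumeration; OR is the sample OR", {
  t0 <- matrix(c(5, 5, 5, 5), 2)
  f0 <- fisher_exact(t0)
  expect_equal(f0$odds_ratio, 1)
  expect_equal(f0$p, 1)

  t1 <- matrix(c(10, 5, 2, 10), 2)      # [[10,2],[5,10]]
  f1 <- fisher_exact(t1)
  expect_equal(f1$odds_ratio, 10)
  expect_equal(f1$p, oracle_fisher_p(t1))
  # stats::fisher.test as an independent cross-check of the p-value
  expect_equal(f1$p, stats::fisher.test(t1)$p.value, tolerance = 1e-12)

  t2 <- matrix(c(3, 0, 0, 3), 2)
  f2 <- fisher_exact(t2)
  expect_true(is.infinite(f2$odds_ratio))
  expect_equal(f2$p, 0.1)               # 20 equally likely tables

  # zero margin: p = 1, OR undefined
  f3 <- fisher_exact(matrix(c(0, 0, 4, 6), 2, byrow = TRUE))
  expect_true(is.na(f3$odds_ratio))
  expect_equal(f3$p, 1)
})

test_that("fisher is symmetric under simultaneous row and column swap", {
  set.seed(12)
  for (rep in 1:20) {
    tab <- matrix(sample(0:12, 4, replace = TRUE), 2)
    a <- fisher_exact(tab)
    b <- fisher_exact(tab[2:1, 2:1])
    expect_equal(a$p, b$p)
    if (is.finite(a$odds_ratio) && !is.na(b$odds_ratio)) {
      expect_equal(a$odds_ratio, b$odds_ratio)
    }
    expect_true(is.na(a$p) || (a$p > 0 && a$p <= 1))
  }
})
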