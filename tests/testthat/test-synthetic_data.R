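small_params <- function(seed, n_genes = 40L, ...) {
  sim_params(n_genes = n_genes, seed = seed, ...)
}

test_that("simulation is reproducible from the seed", {
  d1 <- simulate_dataset(small_params(301L, n_genes = 10L))
  d2 <- simulate_dataset(small_params(301L, n_genes = 10L))
  expect_identical(d1$alignments[[1]]$seqs, d2$alignments[[1]]$seqs)
  expect_identical(d1$snps, d2$snps)
  expect_identical(d1$truth$indels, d2$truth$indels)
  d3 <- simulate_dataset(small_params(302L, n_genes = 10L))
  expect_false(identical(d1$alignments[[1]]$seqs, d3$alignments[[1]]$seqs))
})

test_that("a seed is mandatory and bad parameters fail before generation", {
  expect_error(sim_params(n_genes = 5L), "seed")
  expect_error(sim_params(seed = 1L, gene_length_codons = 100L),
               "gene_length_codons")
  expect_error(sim_params(seed = 1L, upstream_bias = 1.4))
})

test_that("every simulated indel is re-identified exactly by the catalog", {
  ds <- simulate_dataset(small_params(77L, n_genes = 80L))
  cat1 <- classify_indels(ds$alignments)
  expect_true(all(cat1$kept))
  m <- merge(ds$truth$indels, as.data.frame(cat1), by = "gene_id")
  expect_equal(nrow(m), nrow(ds$truth$indels))
  expect_equal(m$configuration.x, m$configuration.y)
  expect_equal(m$type.x, m$type.y)
  expect_equal(m$length_codons.x, m$length_codons.y)
  expect_equal(m$position, m$junction_codon)
})

test_that("neutral indel spectra follow the 1/i law", {
  tab <- simulate_neutral_indel_sfs(2L, 50L, seed = 5L)
  expect_true(all(tab$derived_count == 1L))          # n=2: all singletons

  tab2 <- simulate_neutral_indel_sfs(162L, 5000L, seed = 6L)
  s <- indel_sfs(tab2)
  ne <- neutral_expected_sfs(162L)
  expect_equal(s$mean_freq, ne$mean_freq, tolerance = 0.05)

  expect_identical(simulate_neutral_indel_sfs(10L, 100L, seed = 9L),
                   simulate_neutral_indel_sfs(10L, 100L, seed = 9L))
})

test_that("zero-excess simulations give matched case and control counts", {
  ds <- simulate_dataset(sim_params(
    n_genes = 120L, seed = 404L, lambda_total = 0,
    config_probs = stats::setNames(rep(0.25, 4), c("b", "b'", "d", "d'"))))
  expect_null(ds$truth$excess_events)
  counts <- analyze_catalog(ds$alignments, classify_indels(ds$alignments))
  wl <- walk_length(counts[counts$configuration %in% c("b", "d"), ],
                    counts[counts$configuration %in% c("b'", "d'"), ],
                    B = 400L, seed = 8L)
  expect_true(wl$ci95[1] <= 0 && 0 <= wl$ci95[2])
})

test_that("upstream bias propagates into the excess event record", {
  ds <- simulate_dataset(sim_params(
    n_genes = 100L, seed = 505L, lambda_total = 4, upstream_bias = 0.7,
    config_probs = stats::setNames(c(0.5, 0.5), c("b", "b'"))))
  ev <- ds$truth$excess_events
  expect_gt(nrow(ev), 50L)
  expect_gt(mean(ev$side == "u"), 0.5)
  # distances follow a decaying law: more events close than far
  expect_gt(sum(ev$distance <= 25), sum(ev$distance > 25))
})

test_that("truth bookkeeping weighs shared-branch lineages by half", {
  ds <- simulate_dataset(sim_params(
    n_genes = 60L, seed = 606L, lambda_total = 3,
    config_probs = stats::setNames(c(0.5, 0.5), c("d", "d'"))))
  ev <- ds$truth$excess_events
  n_case <- sum(ds$truth$indels$configuration == "d")
  expect_equal(truth_walk_expectation(ds$truth, "d"),
               0.5 * nrow(ev[ev$distance <= 100, ]) / n_case)
})
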