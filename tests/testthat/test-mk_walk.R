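# fixture: a 40-codon gene with a 1-codon insertion carried by the given
# clade (others gapped), configuration label per the presence pattern
insertion_fixture <- function(carriers, at = 20L) {
  fx <- make_clean_gene(40L)
  gap_codons(fx, setdiff(ALL_SPECIES, carriers), at, 1L)
}

test_that("distance assignment counts codons from the nearest indel edge", {
  indel <- list(mel_codon_start = 15L, mel_codon_end = 16L)
  d <- assign_distance(14L, indel)
  expect_equal(d[c("side", "distance", "bin")],
               list(side = "u", distance = 1L, bin = 1L))
  d <- assign_distance(115L, indel)   # 100 codons downstream
  expect_equal(d[c("side", "distance", "bin")],
               list(side = "d", distance = 100L, bin = 10L))
  expect_null(assign_distance(116L, indel))  # 101 codons away
  expect_null(assign_distance(15L, indel))   # inside the indel
  # a 3-codon indel: edges move with the interval
  wide <- list(mel_codon_start = 10L, mel_codon_end = 13L)
  expect_equal(assign_distance(9L, wide)$distance, 1L)
  expect_equal(assign_distance(13L, wide)$distance, 1L)
  expect_null(assign_distance(11L, wide))
})

test_that("mel-specific configurations count only sec==ere matching sites", {
  fx <- insertion_fixture("mel")               # configuration a
  # distance 3 upstream: mel GTG vs sec ATG with sec==ere -> Dn += 1
  fx <- set_codon(fx, "mel", 17L, "GTG")
  fx <- set_codon(fx, c("sec", "ere"), 17L, "ATG")
  # distance 5 downstream: mel!=sec but sec!=ere -> excluded site
  fx <- set_codon(fx, "mel", 25L, "GAT")
  fx <- set_codon(fx, "sec", 25L, "GCT")
  fx <- set_codon(fx, "ere", 25L, "GGT")
  # distance 7 upstream: fourfold mismatch -> Ds += 1
  fx <- set_codon(fx, "mel", 13L, "GCA")
  ga <- as_gene(fx)
  cat1 <- classify_indels(ga)
  expect_equal(cat1$configuration, "a")
  counts <- analyze_catalog(list(gX = ga), cat1)

  u1 <- counts[counts$side == "u" & counts$bin == 1L, ]
  d1 <- counts[counts$side == "d" & counts$bin == 1L, ]
  expect_equal(u1$Dn_mis, 1)
  expect_equal(u1$Ds_mis, 1)
  expect_equal(d1$Dn_mis, 0)           # sec!=ere site contributes nothing
  expect_equal(u1$aa_subs, 1)          # V vs M at sec==ere codon, weight 1
  expect_equal(d1$aa_subs, 0)
  # the sec!=ere position is excluded from the site totals as well
  expect_equal(d1$n_sites_nondeg + d1$n_sites_fourfold +
                 d1$poly_sites_nondeg * 0, d1$n_sites_nondeg + d1$n_sites_fourfold)
  expect_lt(d1$n_sites_nondeg + d1$n_sites_fourfold, 30)
})

test_that("shared-branch configurations halve amino-acid substitutions", {
  fx <- insertion_fixture(c("mel", "sec"))     # configuration c
  for (k in 0:3) {                             # 4 aa mismatches, bin d1
    fx <- set_codon(fx, "mel", 21L + k, "GTT")
  }
  ga <- as_gene(fx)
  cat1 <- classify_indels(ga)
  expect_equal(cat1$configuration, "c")
  counts <- analyze_catalog(list(gX = ga), cat1)
  d1 <- counts[counts$side == "d" & counts$bin == 1L, ]
  expect_equal(d1$aa_subs, 2.0)                # 4 differences / 2
  expect_equal(d1$Dn_mis, 4)                   # Dn itself is not halved

  # halving-rule linearity: doubling the mismatches doubles aa_subs
  fx2 <- insertion_fixture(c("mel", "sec"))
  for (k in 0:1) fx2 <- set_codon(fx2, "mel", 21L + k, "GTT")
  ga2 <- as_gene(fx2)
  counts2 <- analyze_catalog(list(gX = ga2), classify_indels(ga2))
  expect_equal(2 * counts2[counts2$side == "d" & counts2$bin == 1L, "aa_subs"],
               d1$aa_subs)
})

test_that("polymorphic sites need both alleles in at least two lines", {
  fx <- insertion_fixture("mel")
  ga <- as_gene(fx)
  cat1 <- classify_indels(ga)
  # GCT: pos 2 fourfold (mel allele T), pos 0 nondegenerate (mel allele G)
  snps <- polymorphism_table(data.frame(
    gene_id = "gX",
    codon_index = c(10L, 12L, 14L),
    codon_pos   = c(2L, 0L, 0L),
    A = c(12L, 1L, 5L), C = c(0L, 0L, 0L),
    G = c(0L, 161L, 157L), T = c(150L, 0L, 0L),
    n_called = c(162L, 162L, 162L)), 162L)
  counts <- analyze_catalog(list(gX = ga), cat1, snps)
  u1 <- counts[counts$side == "u" & counts$bin == 1L, ]
  expect_equal(u1$Ps, 1)    # 150/12 fourfold site counted
  expect_equal(u1$Pn, 1)    # 157/5 counted; 161/1 singleton excluded
})

test_that("the two-alleles rule admits 2/2 among 4 called lines", {
  fx <- insertion_fixture("mel")
  ga <- as_gene(fx)
  cat1 <- classify_indels(ga)
  snps <- polymorphism_table(data.frame(
    gene_id = "gX", codon_index = 10L, codon_pos = 2L,
    A = 2L, C = 0L, G = 0L, T = 2L, n_called = 4L), 4L)
  counts <- analyze_catalog(list(gX = ga), cat1, snps)
  expect_equal(sum(counts$Ps), 1)
})

test_that("alpha follows the MK formula with zero-denominator sentinels", {
  expect_equal(mk_alpha(0.01, 0.01, 0.002, 0.008), 0.75)
  expect_equal(mk_alpha(0.002, 0.001, 0.001, 0.001), 0.5)
  expect_equal(mk_alpha(0.01, 0.01, 0.01, 0.01), 0)     # neutral expectation
  expect_true(is.na(mk_alpha(0, 0.01, 0.001, 0.01)))    # Dn = 0
  expect_true(is.na(mk_alpha(0.01, 0, 0.001, 0.01)))    # Ds = 0
  expect_true(is.na(mk_alpha(0.01, 0.01, 0.001, 0)))    # Ps = 0
  expect_equal(mk_alpha(0.01, 0.01, 0, 0.01), 1)        # Pn = 0 is fine
})

test_that("pooled alpha equals per-bin alpha when fractions are identical", {
  rows <- expand.grid(side = c("u", "d"), bin = 1:10,
                      stringsAsFactors = FALSE)
  counts <- do.call(rbind, lapply(c("i1", "i2", "i3"), function(id) {
    cbind(rows, data.frame(
      indel_id = id, n_sites_nondeg = 100, Dn_mis = 2,
      n_sites_fourfold = 50, Ds_mis = 1,
      poly_sites_nondeg = 100, Pn = 1, poly_sites_fourfold = 50, Ps = 1))
  }))
  per_bin_alpha <- mk_alpha(2 / 100, 1 / 50, 1 / 100, 1 / 50)
  pooled <- mk_alpha_pooled(counts, B = 20L, seed = 9L)
  expect_equal(pooled$alpha, per_bin_alpha)
  expect_equal(per_bin_alpha, 0.5)
})

test_that("walk length sums per-bin excesses and is zero for equal sets", {
  mk_counts <- function(ids, val) {
    do.call(rbind, lapply(ids, function(id) {
      data.frame(indel_id = id, side = rep(c("u", "d"), each = 10),
                 bin = rep(1:10, 2), aa_subs = val)
    }))
  }
  case <- mk_counts(c("c1", "c2"), 0.5)
  ctrl <- mk_counts(c("k1", "k2"), 0.5)
  wl <- walk_length(case, ctrl, B = 50L, seed = 2L)
  expect_equal(wl$total, 0)
  expect_equal(sum(wl$per_bin), wl$total)

  case2 <- mk_counts(c("c1", "c2"), 0.75)
  wl2 <- walk_length(case2, ctrl, B = 50L, seed = 2L)
  expect_equal(wl2$total, 20 * 0.25)
  expect_equal(sum(wl2$per_bin), wl2$total)

  # empty input gives the undefined sentinel
  expect_true(is.na(walk_length(case[0, ], ctrl, B = 10L, seed = 1L)$total))
})

test_that("walk-length aggregation over configurations is the sum", {
  expect_equal(combine_walk_components(c(2.60, 2.17)), 4.77)
  expect_equal(combine_walk_components(c(0.33, 0.71)), 1.04)
})

test_that("contingency tables assemble rounded substitution counts", {
  mk_counts <- function(u1, d1, cons_frac) {
    df <- data.frame(indel_id = "i", side = rep(c("u", "d"), each = 10),
                     bin = rep(1:10, 2), aa_subs = 0)
    df$aa_subs[df$side == "u" & df$bin == 1] <- u1
    df$aa_subs[df$side == "d" & df$bin == 1] <- d1
    df$aa_subs_cons <- df$aa_subs * cons_frac
    df
  }
  tabs <- contingency_tables(mk_counts(20, 10, 0.5), mk_counts(10, 10, 0.2))
  expect_equal(unname(tabs$updown),
               matrix(c(20, 10, 10, 10), 2, byrow = TRUE))
  expect_equal(unname(tabs$conservation),
               matrix(c(15, 15, 4, 16), 2, byrow = TRUE))
})

test_that("the two-sample bootstrap CI is seed-deterministic", {
  x <- c(1, 2, 3, 4, 5, 8)
  y <- c(0, 1, 1, 2, 3, 3)
  a <- two_sample_mean_diff_ci(x, y, B = 200L, seed = 7L)
  b <- two_sample_mean_diff_ci(x, y, B = 200L, seed = 7L)
  expect_identical(a$ci95, b$ci95)
  expect_equal(a$point, mean(x) - mean(y))
  expect_true(a$ci95[1] <= a$point && a$point <= a$ci95[2])
})
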