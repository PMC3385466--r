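test_that("gap blocks are maximal constant-presence runs", {
  fx <- make_clean_gene(30L)
  expect_equal(nrow(find_gap_blocks(as_gene(fx))), 0L)

  # one codon gapped in mel only: absent-in-mel presence vector
  fx <- gap_codons(fx, "mel", 10L, 1L)
  blocks <- find_gap_blocks(as_gene(fx))
  expect_equal(nrow(blocks), 1L)
  expect_equal(blocks$presence, "011111")
  expect_equal(blocks$col_start, 30L)
  expect_equal(blocks$col_end, 33L)
  expect_equal(blocks$exonic_len_nt, 3L)

  # adjacent columns with a different presence vector form separate blocks
  fx <- gap_codons(fx, c("mel", "sec"), 11L, 1L)
  blocks <- find_gap_blocks(as_gene(fx))
  expect_equal(nrow(blocks), 2L)
  expect_setequal(blocks$presence, c("011111", "001111"))
})

test_that("blocks spanning an exon border count only the exonic part", {
  fx <- make_clean_gene(30L)
  fx <- gap_codons(fx, "mel", 10L, 2L)    # 6-nt gap, columns 30..36
  # exon ends at column 33: half of the gap is intronic
  ga <- build_gene(fx$codons, "gX",
                   exon_spans = matrix(c(0L, 33L, 60L, 90L), ncol = 2L,
                                       byrow = TRUE))
  blocks <- find_gap_blocks(ga)
  expect_equal(blocks$exonic_len_nt, 3L)
  expect_equal(blocks$col_end - blocks$col_start, 3L)
})

test_that("polarization matches the spec examples", {
  p <- function(s) polarize(s)$configuration
  expect_equal(p("100000"), "a")      # present only in mel
  expect_equal(p("101111"), "b'")     # absent only in sec
  expect_equal(p("110000"), "c")
  expect_equal(p("001111"), "d")
  expect_equal(p("111000"), "e")
  expect_equal(p("111011"), "f'")
  expect_null(polarize("111100"))     # single event, but above the ana split
  expect_null(polarize("100001"))     # discordant outgroups
  expect_null(polarize("010100"))     # needs two events
})

test_that("polarization agrees with exhaustive Dollo-parsimony enumeration", {
  n_config <- 0L
  for (k in 0:63) {
    pres <- as.logical(bitwAnd(k, 2L^(5:0)) > 0L)
    got <- polarize(pres)
    want <- oracle_dollo(pres)
    if (is.na(want)) {
      expect_null(got)
    } else {
      expect_equal(got$configuration, want)
      n_config <- n_config + 1L
    }
  }
  expect_equal(n_config, 12L)
})

test_that("configuration labels are consistent with indel type", {
  ins <- c("a", "a'", "c", "c'", "e", "e'")
  for (i in seq_len(nrow(indelwalk:::CONFIG_TABLE))) {
    row <- indelwalk:::CONFIG_TABLE[i, ]
    expect_equal(row$type,
                 if (row$configuration %in% ins) "insertion" else "deletion")
  }
})

test_that("filters reject frameshifts, dirty flanks and edge indels", {
  base <- function() make_clean_gene(40L)

  # 3-nt gap with clean flanks: kept, length 1 codon
  fx <- gap_codons(base(), "mel", 20L, 1L)
  cat1 <- classify_indels(as_gene(fx))
  expect_true(cat1$kept)
  expect_equal(cat1$configuration, "b")
  expect_equal(cat1$length_codons, 1L)
  expect_equal(cat1$junction_codon, 20L)

  # 4-nt gap (in sec, so the focal frame invariant holds): frameshift
  fx <- base()
  row <- fx$codons[["sec"]]
  row[21] <- "---"
  row[22] <- sub("^.", "-", row[22])
  fx$codons[["sec"]] <- row
  cat2 <- classify_indels(as_gene(fx))
  expect_false(cat2$kept)
  expect_equal(cat2$configuration, "b'")
  expect_equal(cat2$reason, "frameshift")

  # 'N' 7 nt downstream of the gap in ananassae: dirty flank
  fx <- gap_codons(base(), "mel", 20L, 1L)
  fx$codons[["ana"]][23] <- "NCT"       # column 69 = 6 nt after col 63
  cat3 <- classify_indels(as_gene(fx))
  expect_false(cat3$kept)
  expect_equal(cat3$reason, "dirty-flank")

  # a second gap within the 10-nt window: dirty flank (overlap rule)
  fx <- gap_codons(base(), "mel", 20L, 1L)
  fx <- gap_codons(fx, "ere", 22L, 1L)
  cat4 <- classify_indels(as_gene(fx))
  expect_false(any(cat4$kept))
  expect_true(all(cat4$reason == "dirty-flank"))

  # gap at the first codon: window extends past the alignment start
  fx <- gap_codons(base(), "mel", 0L, 1L)
  cat5 <- classify_indels(as_gene(fx))
  expect_false(cat5$kept)
  expect_equal(cat5$reason, "edge")
})

test_that("filtering is order-independent", {
  fxs <- list(gap_codons(make_clean_gene(40L, "g1"), "mel", 20L, 1L),
              gap_codons(make_clean_gene(40L, "g2"), "sec", 15L, 2L),
              gap_codons(make_clean_gene(40L, "g3"), c("mel", "sec"), 25L, 1L))
  alns <- lapply(fxs, as_gene)
  fwd <- classify_indels(alns)
  rev_cat <- classify_indels(rev(alns))
  fwd_sorted <- fwd[order(fwd$gene_id), ]
  rev_sorted <- rev_cat[order(rev_cat$gene_id), ]
  rownames(fwd_sorted) <- rownames(rev_sorted) <- NULL
  expect_equal(fwd_sorted, rev_sorted)
})

test_that("frameshift error bound is the coding/intron ratio", {
  expect_equal(frameshift_error_bound(5, 100), 0.05)
  expect_equal(frameshift_error_bound(0, 50), 0)
  expect_equal(frameshift_error_bound(7, 1000), 0.007)
  expect_true(is.na(frameshift_error_bound(3, 0)))
})

test_that("catalog TSV reports 1-based junctions", {
  fx <- gap_codons(make_clean_gene(40L, "g1"), "mel", 20L, 1L)
  cat1 <- classify_indels(as_gene(fx))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_indel_catalog(cat1, path)
  out <- utils::read.delim(path)
  expect_equal(out$junction, cat1$junction_codon + 1L)
  expect_equal(out$status, "kept")
})
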