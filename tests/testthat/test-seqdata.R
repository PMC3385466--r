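test_that("alignment FASTA round-trip is byte-identical", {
  fx1 <- make_clean_gene(20L, "gene_a")
  fx1 <- set_codon(fx1, "sec", 5L, "GTT")
  fx2 <- make_clean_gene(25L, "gene_b")
  fx2 <- gap_codons(fx2, c("mel"), 10L, 1L)
  alns <- list(gene_a = as_gene(fx1), gene_b = as_gene(fx2))
  dir <- withr::local_tempdir()
  write_alignments(alns, dir)
  back <- read_alignments(dir)
  expect_identical(names(back), c("gene_a", "gene_b"))
  for (g in names(alns)) {
    expect_identical(back[[g]]$seqs[names(alns[[g]]$seqs)], alns[[g]]$seqs)
    expect_identical(back[[g]]$ncol, alns[[g]]$ncol)
  }
})

test_that("malformed alignments are rejected with gene-naming errors", {
  dir <- withr::local_tempdir()
  # ragged: one row shorter
  writeLines(c(">mel", strrep("GCT", 10), ">sec", strrep("GCT", 9)),
             file.path(dir, "ragged.fa"))
  expect_error(read_alignments(dir), "ragged")

  dir2 <- withr::local_tempdir()
  writeLines(c(">mel", strrep("GCT", 10), ">martian", strrep("GCT", 10)),
             file.path(dir2, "g1.fa"))
  expect_error(read_alignments(dir2), "unknown species")

  # focal CDS length 31 nt: skipped with a warning, other genes survive
  dir3 <- withr::local_tempdir()
  writeLines(c(">mel", paste0(strrep("GCT", 10), "A"),
               ">sec", paste0(strrep("GCT", 10), "A")),
             file.path(dir3, "bad.fa"))
  writeLines(c(">mel", strrep("GCT", 10), ">sec", strrep("GCT", 10)),
             file.path(dir3, "good.fa"))
  expect_warning(res <- read_alignments(dir3), "bad")
  expect_identical(names(res), "good")
})

test_that("column count is conserved across species", {
  fx <- make_clean_gene(15L)
  fx <- gap_codons(fx, c("mel", "sec"), 7L, 2L)
  ga <- as_gene(fx)
  widths <- nchar(ga$seqs)
  expect_true(all(widths == widths[1L]))
})

test_that("polymorphism tables validate and round-trip through TSV", {
  rec <- data.frame(gene_id = "g1", codon_index = c(0L, 3L, 7L),
                    codon_pos = c(0L, 2L, 1L),
                    A = c(100L, 0L, 80L), C = c(62L, 150L, 0L),
                    G = c(0L, 12L, 82L), T = c(0L, 0L, 0L),
                    n_called = c(162L, 162L, 162L))
  tab <- polymorphism_table(rec, 162L)
  expect_equal(attr(tab, "sample_size"), 162L)
  expect_equal(tab$n_alleles, c(2, 2, 2))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_polymorphism(tab, path)
  back <- read_polymorphism(snp_path = path)$snps
  expect_equal(attr(back, "sample_size"), 162L)
  expect_equal(back$A, tab$A)
  expect_equal(back$n_called, tab$n_called)

  # invariant violations are hard errors
  bad <- rec; bad$A[1] <- 99L
  expect_error(polymorphism_table(bad, 162L), "sum")
  expect_error(polymorphism_table(rec, 100L), "sample_size")
})

test_that("multi-allelic SNP sites are flagged by allele count", {
  rec <- data.frame(gene_id = "g1", codon_index = 0L, codon_pos = 0L,
                    A = 100L, C = 33L, G = 29L, T = 0L, n_called = 162L)
  tab <- polymorphism_table(rec, 162L)
  expect_equal(tab$n_alleles, 3)
})

test_that("VCF reader separates SNPs and indels and maps coordinates", {
  skip_if_not_installed("vcfR")
  vcf <- withr::local_tempfile(fileext = ".vcf")
  gt_line <- function(chrom, pos, ref, alt, calls) {
    paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", calls),
          collapse = "\t")
  }
  n <- 100L
  calls_snp <- c(rep("1", 12L), rep("0", n - 12L))
  calls_indel <- c(rep("1", 5L), rep("0", n - 5L))
  calls_multi <- c(rep("1", 4L), rep("2", 4L), rep("0", n - 8L))
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "##contig=<ID=chr2L>",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("line", seq_len(n))), collapse = "\t"),
    gt_line("chr2L", 105L, "A", "G", calls_snp),
    gt_line("chr2L", 110L, "A", "C,G", calls_multi),
    gt_line("chr2L", 120L, "ATTT", "A", calls_indel),
    gt_line("chr9X", 999L, "A", "T", calls_snp)
  ), vcf)
  gene_map <- data.frame(gene_id = "g1", chrom = "chr2L", start = 101L,
                         cds_length_nt = 300L)
  res <- read_polymorphism_vcf(vcf, gene_map)
  expect_equal(nrow(res$snps), 1L)
  expect_equal(res$snps$codon_index, 1L)   # offset 4 -> codon 1, pos 1
  expect_equal(res$snps$codon_pos, 1L)
  expect_equal(res$snps$G, 12L)
  # 3-nt deletion at 12/100 lines: one codon, derived count 5
  expect_equal(nrow(res$indels), 1L)
  expect_equal(res$indels$length_codons, 1L)
  expect_equal(res$indels$type, "deletion")
  expect_equal(res$indels$derived_count / res$indels$n_called, 0.05)
  expect_equal(res$dropped$unmappable, 1L)
  expect_equal(res$dropped$multi_allelic, 1L)
})
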