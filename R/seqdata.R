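# Data model: species tree registry, gene alignments, polymorphism tables.
# Internal coordinates are 0-based, half-open; emitted human-readable reports
# are 1-based inclusive.

#' Fixed Drosophila species tree used for indel polarization
#'
#' Returns the registry of species used throughout the analysis: the fixed
#' rooted topology `(((((mel,sec),ere),ana),pse),vir)` over the six focal
#' species (D. melanogaster, D. sechellia, D. erecta, D. ananassae,
#' D. pseudoobscura, D. virilis), and the six basal species used for
#' conservation calls (D. pseudoobscura, D. persimilis, D. willistoni,
#' D. virilis, D. mojavensis, D. grimshawi).
#'
#' @return An object of class `species_tree`: a list with elements
#'   `phylo` (an [ape::read.tree()] phylo object), `newick` (the topology
#'   string), `focal_order` (the six focal species codes, in the fixed
#'   order mel, sec, ere, ana, pse, vir), `basal_six` (species codes used
#'   for conservation classification) and `all_species`.
#' @export
#' @examples
#' tr <- species_tree()
#' tr$focal_order
species_tree <- function() {
  newick <- "(((((mel,sec),ere),ana),pse),vir);"
  structure(list(
    phylo       = ape::read.tree(text = newick),
    newick      = newick,
    focal_order = c("mel", "sec", "ere", "ana", "pse", "vir"),
    basal_six   = c("pse", "per", "wil", "vir", "moj", "gri"),
    all_species = c("mel", "sec", "ere", "ana", "pse", "vir",
                    "per", "wil", "moj", "gri")
  ), class = "species_tree")
}

#' Construct a validated gene alignment
#'
#' A gene alignment holds one gene's aligned coding sequences across the
#' focal and basal species, as equal-length strings over `A,C,G,T,N,-`.
#'
#' @param gene_id Gene identifier.
#' @param seqs Named character vector of aligned sequences; names are
#'   species codes (see [species_tree()]); all strings must have equal
#'   length.  The focal species `mel` is required.
#' @param frame_anchor Alignment column (0-based) of the first codon
#'   position in the focal species.  Default 0.
#' @param exon_spans Two-column integer matrix of focal-species coding
#'   intervals in alignment columns (0-based, half-open).  Default: one
#'   span covering the whole alignment.
#' @return An object of class `gene_alignment`.
#' @export
gene_alignment <- function(gene_id, seqs, frame_anchor = 0L, exon_spans = NULL) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L) {
    stop("ragged alignment in gene '", gene_id, "': row lengths ",
         paste(unique(widths), collapse = ", "))
  }
  ncol <- widths[[1L]]
  if (!("mel" %in% names(seqs))) {
    stop("gene '", gene_id, "': focal species 'mel' missing")
  }
  if (is.null(exon_spans)) {
    exon_spans <- matrix(c(0L, ncol), ncol = 2L)
  }
  exon_spans <- matrix(as.integer(exon_spans), ncol = 2L)
  colnames(exon_spans) <- c("start", "end")
  if (any(exon_spans[, 1] < 0L) || any(exon_spans[, 2] > ncol) ||
      any(exon_spans[, 1] >= exon_spans[, 2])) {
    stop("gene '", gene_id, "': invalid exon spans")
  }
  ga <- structure(list(
    gene_id      = gene_id,
    seqs         = seqs,
    frame_anchor = as.integer(frame_anchor),
    exon_spans   = exon_spans,
    ncol         = as.integer(ncol)
  ), class = "gene_alignment")
  len <- focal_cds_length(ga)
  if (len %% 3L != 0L) {
    stop("gene '", gene_id, "': focal coding length ", len,
         " not a multiple of 3")
  }
  ga
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat("<gene_alignment> ", x$gene_id, ": ", length(x$seqs), " species x ",
      x$ncol, " columns, ", focal_cds_length(x) %/% 3L, " focal codons\n",
      sep = "")
  invisible(x)
}

# character matrix view (species x columns)
aln_matrix <- function(ga, species = names(ga$seqs)) {
  m <- do.call(rbind, strsplit(ga$seqs[species], "", fixed = TRUE))
  rownames(m) <- species
  m
}

# logical vector over columns: TRUE where the column lies in an exon span
exonic_mask <- function(ga) {
  mask <- logical(ga$ncol)
  for (i in seq_len(nrow(ga$exon_spans))) {
    mask[(ga$exon_spans[i, 1] + 1L):ga$exon_spans[i, 2]] <- TRUE
  }
  mask
}

# ungapped focal (mel) coding length in nucleotides
focal_cds_length <- function(ga) {
  chars <- strsplit(ga$seqs[["mel"]], "", fixed = TRUE)[[1L]]
  sum(chars != "-" & exonic_mask(ga))
}

# map focal coding nucleotide position (0-based) -> alignment column (0-based)
focal_column_map <- function(ga) {
  chars <- strsplit(ga$seqs[["mel"]], "", fixed = TRUE)[[1L]]
  which(chars != "-" & exonic_mask(ga)) - 1L
}

#' Read a directory of per-gene aligned FASTA files
#'
#' One FASTA file per gene (`<gene_id>.fa`/`.fasta`); each record header
#' is a species code known to the tree.  Gap character is `-`.  Genes whose
#' ungapped focal coding length is not a multiple of 3 are skipped with a
#' warning; ragged alignments and unknown species are hard errors.
#'
#' @param path Directory containing the FASTA files.
#' @param tree A [species_tree()].
#' @return Named list of [gene_alignment()] objects.
#' @export
read_alignments <- function(path, tree = species_tree()) {
  files <- sort(list.files(path, pattern = "\\.(fa|fasta)$", full.names = TRUE))
  if (length(files) == 0L) stop("no FASTA files found under ", path)
  out <- list()
  for (f in files) {
    gene_id <- sub("\\.(fa|fasta)$", "", basename(f))
    recs <- Biostrings::readBStringSet(f)
    seqs <- as.character(recs)
    names(seqs) <- sub("\\s.*$", "", names(recs))
    unknown <- setdiff(names(seqs), tree$all_species)
    if (length(unknown) > 0L) {
      stop("gene '", gene_id, "': unknown species ",
           paste(unknown, collapse = ", "))
    }
    ga <- tryCatch(gene_alignment(gene_id, seqs), error = function(e) e)
    if (inherits(ga, "error")) {
      if (grepl("not a multiple of 3", conditionMessage(ga))) {
        warning("skipping gene '", gene_id, "': ", conditionMessage(ga),
                call. = FALSE)
        next
      }
      stop(ga)
    }
    out[[gene_id]] <- ga
  }
  out
}

#' Write gene alignments as per-gene FASTA files
#'
#' @param alignments Named list of [gene_alignment()] objects.
#' @param path Output directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_alignments <- function(alignments, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (ga in alignments) {
    f <- file.path(path, paste0(ga$gene_id, ".fa"))
    Biostrings::writeXStringSet(Biostrings::BStringSet(ga$seqs), f, width = 80L)
    files <- c(files, f)
  }
  invisible(files)
}

#' Construct a SNP polymorphism table
#'
#' Within-species polymorphism for the focal species, one row per variable
#' site: `gene_id`, `codon_index` (0-based), `codon_pos` (0-2), allele
#' counts `A,C,G,T` over the called lines, and `n_called`.
#'
#' @param records Data frame with the columns above.
#' @param sample_size Total number of sequenced lines (e.g. 162).
#' @return Object of class `polymorphism_table` (a validated data frame
#'   with a `sample_size` attribute).
#' @export
polymorphism_table <- function(records, sample_size) {
  need <- c("gene_id", "codon_index", "codon_pos", "A", "C", "G", "T", "n_called")
  stopifnot(all(need %in% names(records)))
  records <- as.data.frame(records)[need]
  counts <- as.matrix(records[, c("A", "C", "G", "T")])
  if (any(counts < 0)) stop("negative allele count")
  if (any(rowSums(counts) != records$n_called)) {
    stop("allele counts do not sum to n_called")
  }
  if (any(records$n_called > sample_size)) {
    stop("n_called exceeds sample_size")
  }
  records$n_alleles <- rowSums(counts > 0)
  attr(records, "sample_size") <- as.integer(sample_size)
  class(records) <- c("polymorphism_table", "data.frame")
  records
}

#' Construct a polymorphic-indel table
#'
#' One row per polarized polymorphic indel: `gene_id`, `position`
#' (0-based focal codon), `length_codons`, `type` (`insertion`/`deletion`),
#' `derived_count`, `n_called`.
#'
#' @param records Data frame with the columns above.
#' @param sample_size Total number of lines.
#' @return Object of class `indel_polymorphism_table`.
#' @export
indel_polymorphism_table <- function(records, sample_size) {
  need <- c("gene_id", "position", "length_codons", "type",
            "derived_count", "n_called")
  stopifnot(all(need %in% names(records)))
  records <- as.data.frame(records)[need]
  if (any(records$length_codons < 1L)) stop("indel length < 1 codon")
  if (any(records$derived_count > records$n_called)) {
    stop("derived count exceeds n_called")
  }
  if (!all(records$type %in% c("insertion", "deletion"))) {
    stop("type must be 'insertion' or 'deletion'")
  }
  attr(records, "sample_size") <- as.integer(sample_size)
  class(records) <- c("indel_polymorphism_table", "data.frame")
  records
}

#' Read polymorphism tables from the TSV dialect
#'
#' SNP dialect: tab-separated, header
#' `gene_id codon_index codon_pos A C G T n_called`; an optional first
#' comment line `#sample_size=<n>`.  Indel dialect: header
#' `gene_id position length_codons type derived_count n_called`.
#'
#' @param snp_path Path to the SNP TSV (or `NULL`).
#' @param indel_path Path to the indel TSV (or `NULL`).
#' @param sample_size Override for the sample size; default is taken from
#'   the `#sample_size=` header line, falling back to `max(n_called)`.
#' @return List with elements `snps` ([polymorphism_table()] or `NULL`) and
#'   `indels` ([indel_polymorphism_table()] or `NULL`).
#' @export
read_polymorphism <- function(snp_path = NULL, indel_path = NULL,
                              sample_size = NULL) {
  read_one <- function(path, ctor) {
    first <- readLines(path, n = 1L)
    n <- sample_size
    if (is.null(n) && grepl("^#sample_size=", first)) {
      n <- as.integer(sub("^#sample_size=", "", first))
    }
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    if (is.null(n)) n <- max(df$n_called)
    ctor(df, n)
  }
  list(
    snps   = if (!is.null(snp_path)) read_one(snp_path, polymorphism_table),
    indels = if (!is.null(indel_path)) read_one(indel_path, indel_polymorphism_table)
  )
}

#' Read focal-species polymorphism from a VCF
#'
#' Accepts a VCF 4.x with per-line genotypes for the focal species
#' (inbred lines treated as haploid: the first allele of each genotype is
#' used).  Positions are mapped to focal-species codon coordinates through
#' `gene_map`.  SNPs and indels are separated; multi-allelic SNP sites are
#' flagged and skipped from the SNP table with a reported count;
#' unmappable positions are dropped with a reported count.
#'
#' @param path VCF file.
#' @param gene_map Data frame with columns `gene_id`, `chrom`, `start`
#'   (1-based genomic position of the first coding nucleotide) and
#'   `cds_length_nt`; genes are assumed colinear with the + strand.
#' @param sample_size Number of lines in the panel; default the number of
#'   genotype columns.
#' @return As [read_polymorphism()], plus a `dropped` count list.
#' @export
read_polymorphism_vcf <- function(path, gene_map, sample_size = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v)
  # haploid resolution: first allele of each genotype call
  al <- substr(gt, 1L, 1L)
  al[al == "."] <- NA_character_
  if (is.null(sample_size)) sample_size <- ncol(al)

  n_unmapped <- 0L; n_multi <- 0L
  snp_rows <- list(); indel_rows <- list()
  for (i in seq_len(nrow(fix))) {
    pos <- as.integer(fix$POS[i])
    hit <- which(gene_map$chrom == fix$CHROM[i] &
                 pos >= gene_map$start &
                 pos < gene_map$start + gene_map$cds_length_nt)
    if (length(hit) != 1L) { n_unmapped <- n_unmapped + 1L; next }
    off <- pos - gene_map$start[hit]           # 0-based coding offset
    ref <- fix$REF[i]
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1L]]
    calls <- al[i, ]
    called <- !is.na(calls)
    if (nchar(ref) == 1L && all(nchar(alts) == 1L)) {
      alleles <- c(ref, alts)
      if (length(alleles) > 2L) { n_multi <- n_multi + 1L; next }
      cnt <- c(A = 0L, C = 0L, G = 0L, T = 0L)
      tab <- table(factor(alleles[as.integer(calls[called]) + 1L],
                          levels = c("A", "C", "G", "T")))
      cnt[names(tab)] <- as.integer(tab)
      snp_rows[[length(snp_rows) + 1L]] <- data.frame(
        gene_id = gene_map$gene_id[hit],
        codon_index = off %/% 3L, codon_pos = off %% 3L,
        A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]], T = cnt[["T"]],
        n_called = sum(called), stringsAsFactors = FALSE)
    } else if (length(alts) == 1L) {
      d_nt <- abs(nchar(alts) - nchar(ref))
      if (d_nt == 0L || d_nt %% 3L != 0L) next   # frameshifting: counted elsewhere
      type <- if (nchar(alts) > nchar(ref)) "insertion" else "deletion"
      derived <- sum(calls[called] == "1")
      indel_rows[[length(indel_rows) + 1L]] <- data.frame(
        gene_id = gene_map$gene_id[hit],
        position = off %/% 3L, length_codons = d_nt %/% 3L,
        type = type, derived_count = derived, n_called = sum(called),
        stringsAsFactors = FALSE)
    }
  }
  list(
    snps = if (length(snp_rows))
      polymorphism_table(do.call(rbind, snp_rows), sample_size),
    indels = if (length(indel_rows))
      indel_polymorphism_table(do.call(rbind, indel_rows), sample_size),
    dropped = list(unmappable = n_unmapped, multi_allelic = n_multi)
  )
}

#' Write polymorphism tables in the TSV dialect
#'
#' @param tab A [polymorphism_table()] or [indel_polymorphism_table()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_polymorphism <- function(tab, path) {
  df <- as.data.frame(tab)
  df$n_alleles <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#sample_size=", attr(tab, "sample_size")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Fraction-of-lines-missing rule: a polymorphic site (SNP or indel) is
# usable only when at least half the panel was called.
passes_missingness <- function(n_called, sample_size) {
  n_called >= sample_size / 2
}
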