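# Indel catalog: gap-block detection, polarization on the fixed topology,
# and filtering (frame preservation, clean 10-nt flanks).

# The twelve phylogenetic configurations.  Presence vectors are over the
# focal species in fixed order (mel, sec, ere, ana, pse, vir); "1" = the
# species carries the sequence.  Unprimed labels: the indel occurred in the
# clade containing D. melanogaster; primed: in the sister clade.
# a,c,e (+primes) are insertions; b,d,f (+primes) deletions.
CONFIG_TABLE <- data.frame(
  configuration = c("a", "a'", "b", "b'",
                    "c", "c'", "d", "d'",
                    "e", "e'", "f", "f'"),
  presence = c("100000", "010000", "011111", "101111",
               "110000", "001000", "001111", "110111",
               "111000", "000100", "000111", "111011"),
  type = c("insertion", "insertion", "deletion", "deletion",
           "insertion", "insertion", "deletion", "deletion",
           "insertion", "insertion", "deletion", "deletion"),
  in_focal_lineage = c(TRUE, FALSE, TRUE, FALSE,
                       TRUE, FALSE, TRUE, FALSE,
                       TRUE, FALSE, TRUE, FALSE),
  # branch carrying the single gain/loss event
  branch = c("mel", "sec", "mel", "sec",
             "melsec", "ere", "melsec", "ere",
             "melsecere", "ana", "melsecere", "ana"),
  stringsAsFactors = FALSE
)

#' Find maximal constant-presence gap blocks in a gene alignment
#'
#' Scans alignment columns for runs where the presence/absence pattern over
#' the six focal species is constant and at least one species is absent
#' (and at least one present).  Runs are truncated to their exonic part;
#' the exonic column count is what enters the frame-preservation test
#' downstream.
#'
#' @param aln A [gene_alignment()].
#' @param tree A [species_tree()].
#' @return Data frame with one row per block: `gene_id`, `col_start`,
#'   `col_end` (0-based, half-open, exonic part), `exonic_len_nt`,
#'   `presence` (string of 0/1 over mel,sec,ere,ana,pse,vir).
#' @export
find_gap_blocks <- function(aln, tree = species_tree()) {
  sp <- tree$focal_order
  missing_sp <- setdiff(sp, names(aln$seqs))
  if (length(missing_sp) > 0L) {
    stop("gene '", aln$gene_id, "': focal species absent from alignment: ",
         paste(missing_sp, collapse = ", "))
  }
  m <- aln_matrix(aln, sp)
  present <- m != "-"
  # integer key 0..63 per column; 63 = all six present
  key <- as.integer(colSums(present * 2L^(5:0)))
  ex <- exonic_mask(aln)

  r <- rle(key)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != 63L & r$values != 0L
  out <- list()
  for (i in which(keep)) {
    cols <- starts[i]:ends[i]
    ex_cols <- cols[ex[cols]]
    if (length(ex_cols) == 0L) next
    out[[length(out) + 1L]] <- data.frame(
      gene_id = aln$gene_id,
      col_start = min(ex_cols) - 1L,
      col_end = max(ex_cols),
      exonic_len_nt = length(ex_cols),
      presence = paste(as.integer(present[, cols[1L]]), collapse = ""),
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0L) {
    return(data.frame(gene_id = character(0), col_start = integer(0),
                      col_end = integer(0), exonic_len_nt = integer(0),
                      presence = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, out)
}

#' Polarize a presence vector into a phylogenetic configuration
#'
#' Uses Dollo parsimony on the fixed topology
#' `(((((mel,sec),ere),ana),pse),vir)` with both outgroups
#' (D. pseudoobscura and D. virilis) required to agree: if both carry the
#' sequence the ancestral state is presence and absences are deletions; if
#' both lack it the ancestral state is absence and presences are
#' insertions.  Exactly 12 of the 64 presence vectors correspond to a
#' single gain/loss event on one of the branches depicted by the
#' configurations `a`-`f'`; all other vectors (multiple events, discordant
#' outgroups, or events predating the D. ananassae split) are rejected.
#'
#' @param presence Logical vector of length 6 over (mel, sec, ere, ana,
#'   pse, vir), or a 6-character string of 0/1.
#' @return A one-row data frame with `configuration`, `type`,
#'   `in_focal_lineage`, `branch`; or `NULL` when the vector is rejected.
#' @export
#' @examples
#' polarize(c(TRUE, FALSE, FALSE, FALSE, FALSE, FALSE))  # configuration a
polarize <- function(presence) {
  if (is.character(presence)) {
    key <- presence
  } else {
    stopifnot(length(presence) == 6L)
    key <- paste(as.integer(presence), collapse = "")
  }
  i <- match(key, CONFIG_TABLE$presence)
  if (is.na(i)) return(NULL)
  CONFIG_TABLE[i, c("configuration", "type", "in_focal_lineage", "branch")]
}

#' Build the filtered indel catalog for a set of gene alignments
#'
#' Detects gap blocks, polarizes each, and applies the filters: the exonic
#' gap length must be a multiple of 3 (frame-preserving), and the `window`
#' alignment columns flanking the block on each side must contain only
#' A/C/G/T — no gaps and no ambiguity codes — in all six focal species,
#' which also excludes coincident or overlapping indels from other clades.
#'
#' @param alignments List of [gene_alignment()] objects.
#' @param tree A [species_tree()].
#' @param window Flank width in nucleotides (alignment columns); default 10.
#' @return Data frame (class `indel_catalog`), one row per candidate block:
#'   coordinates, presence, configuration (`NA` when unpolarizable), type,
#'   `in_focal_lineage`, `length_codons`, focal codon interval
#'   `mel_codon_start`/`mel_codon_end` (0-based half-open; empty when the
#'   focal species lacks the material), `junction_codon`, `kept`, `reason`.
#' @export
classify_indels <- function(alignments, tree = species_tree(), window = 10L) {
  if (inherits(alignments, "gene_alignment")) alignments <- list(alignments)
  rows <- list()
  for (aln in alignments) {
    blocks <- find_gap_blocks(aln, tree)
    if (nrow(blocks) == 0L) next
    m <- aln_matrix(aln, tree$focal_order)
    clean_col <- colSums(m == "A" | m == "C" | m == "G" | m == "T") == 6L
    # mel coding-nucleotide index per column (NA where mel gapped/non-exonic)
    mel_pos_at_col <- rep(NA_integer_, aln$ncol)
    map <- focal_column_map(aln)          # 0-based positions -> columns
    mel_pos_at_col[map + 1L] <- seq_along(map) - 1L
    n_mel_nt <- length(map)

    for (b in seq_len(nrow(blocks))) {
      blk <- blocks[b, ]
      pol <- polarize(blk$presence)
      mel_present <- substr(blk$presence, 1L, 1L) == "1"
      # focal codon interval of the indel material / junction codon
      if (mel_present) {
        pos_in_block <- mel_pos_at_col[(blk$col_start + 1L):blk$col_end]
        pos_in_block <- pos_in_block[!is.na(pos_in_block)]
        cs <- min(pos_in_block) %/% 3L
        ce <- max(pos_in_block) %/% 3L + 1L
        junction <- cs
      } else {
        after <- mel_pos_at_col[(blk$col_end + 1L):aln$ncol]
        after <- after[!is.na(after)]
        junction <- if (length(after)) after[1L] %/% 3L else n_mel_nt %/% 3L
        cs <- ce <- junction
      }
      reason <- NA_character_
      if (is.null(pol)) {
        reason <- "polarization"
      } else if (blk$exonic_len_nt %% 3L != 0L) {
        reason <- "frameshift"
      } else if (blk$col_start - window < 0L ||
                 blk$col_end + window > aln$ncol) {
        reason <- "edge"
      } else {
        flank <- c((blk$col_start - window + 1L):blk$col_start,
                   (blk$col_end + 1L):(blk$col_end + window))
        if (!all(clean_col[flank])) reason <- "dirty-flank"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = aln$gene_id,
        col_start = blk$col_start, col_end = blk$col_end,
        exonic_len_nt = blk$exonic_len_nt,
        presence = blk$presence,
        configuration = if (is.null(pol)) NA_character_ else pol$configuration,
        type = if (is.null(pol)) NA_character_ else pol$type,
        in_focal_lineage = if (is.null(pol)) NA else pol$in_focal_lineage,
        length_codons = blk$exonic_len_nt %/% 3L,
        mel_codon_start = cs, mel_codon_end = ce,
        junction_codon = junction,
        kept = is.na(reason),
        reason = reason,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    cat_df <- data.frame(gene_id = character(0), col_start = integer(0),
                         col_end = integer(0), exonic_len_nt = integer(0),
                         presence = character(0),
                         configuration = character(0), type = character(0),
                         in_focal_lineage = logical(0),
                         length_codons = integer(0),
                         mel_codon_start = integer(0),
                         mel_codon_end = integer(0),
                         junction_codon = integer(0),
                         kept = logical(0), reason = character(0),
                         stringsAsFactors = FALSE)
  } else {
    cat_df <- do.call(rbind, rows)
  }
  class(cat_df) <- c("indel_catalog", "data.frame")
  cat_df
}

#' Upper bound on the indel-call error frequency
#'
#' The ratio of frameshifting indels in coding regions to indels of length
#' not a multiple of three in short introns.  Frameshifting coding indels
#' are overwhelmingly errors (true ones are removed by selection), so this
#' ratio bounds the error rate of the frame-preserving calls from above.
#'
#' @param coding_frameshift_count Frameshifting indels called in coding
#'   regions.
#' @param intron_non3_count Non-multiple-of-three indels called in short
#'   introns.
#' @return The ratio, or `NA_real_` when the denominator is zero.
#' @export
frameshift_error_bound <- function(coding_frameshift_count, intron_non3_count) {
  if (intron_non3_count <= 0) return(NA_real_)
  coding_frameshift_count / intron_non3_count
}

#' Write the indel catalog as TSV (1-based codon coordinates)
#'
#' @param catalog An [classify_indels()] result.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_indel_catalog <- function(catalog, path) {
  df <- as.data.frame(catalog)
  out <- data.frame(
    gene_id = df$gene_id,
    junction = df$junction_codon + 1L,
    length_codons = df$length_codons,
    type = df$type,
    configuration = df$configuration,
    status = ifelse(df$kept, "kept", "rejected"),
    reason = ifelse(df$kept, "", df$reason),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tabulate kept indels by configuration and length
#'
#' Summary matrix in the style of a length-by-configuration table:
#' configurations as rows, codon lengths 1-4 and `5+` as columns.
#'
#' @param catalog An [classify_indels()] result.
#' @return Integer matrix, 12 x 5.
#' @export
catalog_length_table <- function(catalog) {
  kept <- catalog[catalog$kept, ]
  lens <- pmin(kept$length_codons, 5L)
  tab <- table(factor(kept$configuration, levels = CONFIG_TABLE$configuration),
               factor(lens, levels = 1:5))
  m <- unclass(tab)
  colnames(m) <- c("1", "2", "3", "4", "5+")
  m
}
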