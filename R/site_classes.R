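# Site classification: codon degeneracy under the standard genetic code,
# conservation among the six basal species, clean-flank eligibility.

NUCS <- c("A", "C", "G", "T")

# translate a vector of codon strings; NA for anything not a clean codon
translate_codons <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa
}

# Degeneracy lookup, built once: 64 codons x positions 1..3.
# A position is "nondegenerate" when every single-nucleotide change alters
# the amino acid, "fourfold" when none does.  Positions where any change
# would create a stop codon are classed "other", as are stop codons.
build_degeneracy_table <- function() {
  code <- Biostrings::GENETIC_CODE
  codons <- names(code)
  tab <- matrix("other", nrow = 64L, ncol = 3L, dimnames = list(codons, NULL))
  for (cd in codons) {
    if (code[[cd]] == "*") next
    for (p in 1:3) {
      alts <- vapply(setdiff(NUCS, substr(cd, p, p)), function(n) {
        x <- cd; substr(x, p, p) <- n; x
      }, character(1))
      aa_alt <- code[alts]
      if (any(aa_alt == "*")) next                       # stop-adjacent
      n_change <- sum(aa_alt != code[[cd]])
      tab[cd, p] <- if (n_change == 3L) "nondegenerate"
                    else if (n_change == 0L) "fourfold" else "other"
    }
  }
  tab
}

.degeneracy_env <- new.env(parent = emptyenv())

degeneracy_table <- function() {
  if (is.null(.degeneracy_env$tab)) .degeneracy_env$tab <- build_degeneracy_table()
  .degeneracy_env$tab
}

#' Degeneracy class of a codon position
#'
#' Under the standard genetic code: `nondegenerate` when all three
#' alternative nucleotides at the position change the encoded amino acid,
#' `fourfold` when none does, and `other` otherwise.  Only nondegenerate
#' sites enter the non-synonymous counts and only fourfold sites the
#' synonymous counts; `other` sites are excluded from both.  Positions at
#' which any substitution would create a stop codon, stop codons
#' themselves, and codons containing gaps or ambiguity characters are all
#' classed `other`.
#'
#' @param codon Character vector of 3-letter codons (focal species).
#' @param pos Within-codon position(s), 0-2 (recycled).
#' @return Character vector: `"nondegenerate"`, `"fourfold"` or `"other"`.
#' @export
#' @examples
#' codon_site_degeneracy("GGG", 2)  # fourfold
#' codon_site_degeneracy("ATG", 2)  # nondegenerate
codon_site_degeneracy <- function(codon, pos) {
  n <- max(length(codon), length(pos))
  codon <- rep_len(toupper(codon), n)
  pos <- rep_len(as.integer(pos), n)
  stopifnot(all(pos %in% 0:2))
  tab <- degeneracy_table()
  out <- rep("other", n)
  ok <- codon %in% rownames(tab)
  idx <- cbind(match(codon[ok], rownames(tab)), pos[ok] + 1L)
  out[ok] <- tab[idx]
  out
}

#' Is an amino-acid column conservative among the basal species?
#'
#' A site is conservative when the residue is invariant across the six
#' basal species; any gap or unknown residue makes the call
#' non-conservative.
#'
#' @param residues Character vector of six single-letter amino acids.
#' @return Logical scalar.
#' @export
is_conservative <- function(residues) {
  stopifnot(length(residues) == 6L)
  ok <- residues %in% setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z"))
  all(ok) && length(unique(residues)) == 1L
}

# Per-column flag: A/C/G/T in all six focal species
clean_columns <- function(aln, tree = species_tree()) {
  m <- aln_matrix(aln, tree$focal_order)
  colSums(m == "A" | m == "C" | m == "G" | m == "T") == 6L
}

# Eligibility per alignment column with respect to a focal gap block
# [block_start, block_end): the `window` columns each side of the column
# (and the column itself) must be clean in all six focal species, except
# that columns inside the focal block are exempt.
eligibility_flags <- function(aln, tree = species_tree(),
                              block_start = 0L, block_end = 0L,
                              window = 10L) {
  dirty <- as.integer(!clean_columns(aln, tree))
  if (block_end > block_start) {
    dirty[(block_start + 1L):block_end] <- 0L
  }
  cs <- cumsum(dirty)
  nc <- aln$ncol
  cols <- seq_len(nc)                    # 1-based
  lo <- cols - window
  hi <- cols + window
  ok_range <- lo >= 1L & hi <= nc
  wsum <- rep(NA_integer_, nc)
  wsum[ok_range] <- cs[hi[ok_range]] - c(0L, cs)[lo[ok_range]]
  eligible <- ok_range & wsum == 0L
  eligible
}

#' Is a site eligible for counting, given a focal indel?
#'
#' A nucleotide site enters the divergence/polymorphism counts only when,
#' in each of the six focal species, the `window` nucleotides to its left
#' and right (alignment columns) are gap-free and A/C/G/T-only; the only
#' gaps tolerated are the columns of the focal indel's own gap block.
#'
#' @param aln A [gene_alignment()].
#' @param site_col Alignment column of the site (0-based).
#' @param block_start,block_end Focal gap block columns (0-based,
#'   half-open); use `0,0` for no block.
#' @param tree A [species_tree()].
#' @param window Flank width, nucleotides (default 10).
#' @return Logical scalar.
#' @export
site_eligible <- function(aln, site_col, block_start = 0L, block_end = 0L,
                          tree = species_tree(), window = 10L) {
  flags <- eligibility_flags(aln, tree, block_start, block_end, window)
  flags[site_col + 1L]
}

#' Per-site and per-codon classification table for one gene
#'
#' Builds the focal-species site table used by the counting routines: one
#' row per focal coding nucleotide with its alignment column, codon
#' coordinates, the aligned nucleotides of mel/sec/ere, and the degeneracy
#' class of the focal codon position; plus a per-codon table with the
#' aligned mel/sec/ere codons, their residues, and the basal-species
#' conservation call.
#'
#' @param aln A [gene_alignment()].
#' @param tree A [species_tree()].
#' @return List with data frames `sites` (columns `pos`, `col`,
#'   `codon_index`, `codon_pos`, `mel`, `sec`, `ere`, `degeneracy`) and
#'   `codons` (columns `codon_index`, `mel_codon`, `sec_codon`,
#'   `ere_codon`, `mel_aa`, `sec_aa`, `ere_aa`, `conservative`).
#' @export
gene_site_table <- function(aln, tree = species_tree()) {
  map <- focal_column_map(aln)           # 0-based columns per coding pos
  n_nt <- length(map)
  n_cod <- n_nt %/% 3L
  m <- aln_matrix(aln)
  get_row <- function(spp) if (spp %in% rownames(m)) m[spp, map + 1L]
                           else rep(NA_character_, n_nt)
  mel <- get_row("mel"); sec <- get_row("sec"); ere <- get_row("ere")

  codon_of <- function(x) {
    cm <- matrix(x[seq_len(3L * n_cod)], nrow = 3L)
    out <- paste0(cm[1, ], cm[2, ], cm[3, ])
    out[!grepl("^[ACGT]{3}$", out)] <- NA_character_
    out
  }
  mel_cod <- codon_of(mel); sec_cod <- codon_of(sec); ere_cod <- codon_of(ere)

  codon_index <- (seq_len(n_nt) - 1L) %/% 3L
  codon_pos <- (seq_len(n_nt) - 1L) %% 3L
  degeneracy <- rep("other", n_nt)
  has_cod <- !is.na(mel_cod[codon_index + 1L])
  degeneracy[has_cod] <- codon_site_degeneracy(mel_cod[codon_index[has_cod] + 1L],
                                               codon_pos[has_cod])

  # conservation from the basal six species, at the focal codon's columns
  basal <- tree$basal_six
  cons <- rep(FALSE, n_cod)
  if (all(basal %in% rownames(m))) {
    aas <- matrix(NA_character_, nrow = 6L, ncol = n_cod)
    for (i in seq_along(basal)) {
      cod <- codon_of(m[basal[i], map + 1L])
      aas[i, ] <- translate_codons(cod)
    }
    ok <- colSums(is.na(aas)) == 0L
    cons[ok] <- apply(aas[, ok, drop = FALSE], 2L,
                      function(a) length(unique(a)) == 1L && all(a != "*"))
  }

  list(
    sites = data.frame(
      pos = seq_len(n_nt) - 1L, col = map,
      codon_index = codon_index, codon_pos = codon_pos,
      mel = mel, sec = sec, ere = ere,
      degeneracy = degeneracy, stringsAsFactors = FALSE),
    codons = data.frame(
      codon_index = seq_len(n_cod) - 1L,
      mel_codon = mel_cod, sec_codon = sec_cod, ere_codon = ere_cod,
      mel_aa = translate_codons(mel_cod),
      sec_aa = translate_codons(sec_cod),
      ere_aa = translate_codons(ere_cod),
      conservative = cons, stringsAsFactors = FALSE)
  )
}
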