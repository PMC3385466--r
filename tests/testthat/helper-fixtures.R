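# Fixtures are built in code; oracles are coded independently of the
# package internals (seqinr translation, explicit enumeration).

ALL_SPECIES <- c("mel", "sec", "ere", "ana", "pse", "vir",
                 "per", "wil", "moj", "gri")

# build a gene_alignment from per-species codon vectors ("---" = gap codon)
build_gene <- function(codons_by_species, gene_id = "gX", ...) {
  seqs <- vapply(codons_by_species, paste, "", collapse = "")
  gene_alignment(gene_id, seqs, ...)
}

# clean alignment: all species identical, filled with a neutral codon
clean_codons <- function(n_codons, fill = "GCT") rep(fill, n_codons)

make_clean_gene <- function(n_codons = 30L, gene_id = "gX",
                            species = ALL_SPECIES, fill = "GCT") {
  cods <- lapply(stats::setNames(species, species),
                 function(s) clean_codons(n_codons, fill))
  list(codons = cods, gene_id = gene_id)
}

# replace codon (0-based index) in selected species
set_codon <- function(fx, species, codon_index, value) {
  for (s in species) fx$codons[[s]][codon_index + 1L] <- value
  fx
}

# turn codons [at, at+len) into gaps for the given species
gap_codons <- function(fx, species, at, len = 1L) {
  for (s in species) {
    fx$codons[[s]][(at + 1L):(at + len)] <- strrep("-", 3L)
  }
  fx
}

as_gene <- function(fx, ...) build_gene(fx$codons, fx$gene_id, ...)

# ---- independent oracles -------------------------------------------------

oracle_translate <- function(codon) {
  if (!grepl("^[ACGT]{3}$", codon)) return(NA_character_)
  seqinr::translate(strsplit(codon, "")[[1]])
}

oracle_degeneracy <- function(codon, pos) {   # pos 0-based
  if (!grepl("^[ACGT]{3}$", codon)) return("other")
  aa0 <- oracle_translate(codon)
  if (aa0 == "*") return("other")
  alts <- setdiff(c("A", "C", "G", "T"), substr(codon, pos + 1, pos + 1))
  aa <- vapply(alts, function(n) {
    x <- codon
    substr(x, pos + 1, pos + 1) <- n
    oracle_translate(x)
  }, "")
  if (any(aa == "*")) return("other")
  nd <- sum(aa != aa0)
  if (nd == 3) "nondegenerate" else if (nd == 0) "fourfold" else "other"
}

# Dollo-parsimony enumeration over the branches the configurations depict
oracle_dollo <- function(presence) {  # logical, (mel,sec,ere,ana,pse,vir)
  sp <- c("mel", "sec", "ere", "ana", "pse", "vir")
  names(presence) <- sp
  branches <- list(mel = "mel", sec = "sec", ere = "ere", ana = "ana",
                   melsec = c("mel", "sec"),
                   melsecere = c("mel", "sec", "ere"))
  labels <- list(mel = c(ins = "a", del = "b"),
                 sec = c(ins = "a'", del = "b'"),
                 melsec = c(ins = "c", del = "d"),
                 ere = c(ins = "c'", del = "d'"),
                 melsecere = c(ins = "e", del = "f"),
                 ana = c(ins = "e'", del = "f'"))
  hits <- character(0)
  for (br in names(branches)) {
    clade <- branches[[br]]
    ins_vec <- sp %in% clade            # gained once on the branch
    del_vec <- !(sp %in% clade)         # lost once on the branch
    if (identical(unname(presence), ins_vec)) hits <- c(hits, labels[[br]]["ins"])
    if (identical(unname(presence), del_vec)) hits <- c(hits, labels[[br]]["del"])
  }
  if (length(hits) == 1L) unname(hits) else NA_character_
}

oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  pr <- function(x) choose(r1, x) * choose(r2, c1 - x) / choose(n, c1)
  xs <- max(0, c1 - r2):min(r1, c1)
  ps <- vapply(xs, pr, 0)
  sum(ps[ps <= pr(a) * (1 + 1e-7)])
}

# Tajima's D from explicit pairwise haplotype comparisons
oracle_tajima <- function(counts, n) {
  S <- sum(counts)
  if (S == 0) return(NA_real_)
  haps <- matrix(0L, nrow = n, ncol = S)
  k <- 1L
  for (i in seq_along(counts)) {
    for (r in seq_len(counts[i])) {
      haps[seq_len(i), k] <- 1L
      k <- k + 1L
    }
  }
  prs <- utils::combn(n, 2)
  pi <- mean(apply(prs, 2, function(p) sum(haps[p[1], ] != haps[p[2], ])))
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  num <- pi - S / a1
  den <- sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
  # n <= 3 degenerates to 0/0 (pi always equals theta_W): convention 0
  if (den == 0 && num == 0) return(0)
  num / den
}

oracle_spearman_p <- function(x, y) {
  perms <- e1071::permutations(length(y))
  rho_obs <- stats::cor(x, y, method = "spearman")
  rhos <- apply(perms, 1, function(p) stats::cor(x, y[p], method = "spearman"))
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}
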