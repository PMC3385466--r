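# Distance-binned divergence/polymorphism counting along the
# D. melanogaster lineage, McDonald-Kreitman alpha, and the adaptive
# walk-length estimator.

# configurations whose divergence counting is focal-lineage specific
# (indel after the mel-sec split): count mel-vs-sec mismatches only at
# sites matching between sec and ere, weight 1.  For the remaining
# configurations both the mel and sec lineages carry (or lack) the indel,
# so mel-vs-sec differences are counted at all sites and amino-acid
# substitution counts are halved.
MEL_SPECIFIC_CONFIGS <- c("a", "a'", "b", "b'")

#' Distance bin of a codon relative to an indel
#'
#' Distance is counted in codons from the nearest indel edge (the adjacent
#' codon has distance 1); the side is upstream (N-terminal) or downstream
#' (C-terminal).  Codons inside the indel and codons farther than
#' `max_dist` are out of range.
#'
#' @param site_codon Focal-species codon index (0-based).
#' @param indel One row of an [classify_indels()] catalog (needs
#'   `mel_codon_start`, `mel_codon_end`).
#' @param max_dist Maximum distance in codons (default 100).
#' @param bin_width Bin width in codons (default 10).
#' @return List with `side` (`"u"`/`"d"`), `distance`, `bin` (1-based), or
#'   `NULL` when out of range or inside the indel.
#' @export
assign_distance <- function(site_codon, indel, max_dist = 100L,
                            bin_width = 10L) {
  cs <- indel$mel_codon_start; ce <- indel$mel_codon_end
  if (site_codon >= cs && site_codon < ce) return(NULL)
  if (site_codon < cs) {
    side <- "u"; d <- cs - site_codon
  } else {
    side <- "d"; d <- site_codon - ce + 1L
  }
  if (d > max_dist) return(NULL)
  list(side = side, distance = d, bin = as.integer(ceiling(d / bin_width)))
}

# vectorized: codon distances/sides for a vector of codon indices
codon_distances <- function(codons, cs, ce, max_dist = 100L) {
  side <- ifelse(codons < cs, "u", ifelse(codons >= ce, "d", NA))
  d <- ifelse(codons < cs, cs - codons,
              ifelse(codons >= ce, codons - ce + 1L, NA_integer_))
  d[!is.na(d) & d > max_dist] <- NA_integer_
  side[is.na(d)] <- NA_character_
  list(side = side, distance = d)
}

# empty per-bin scaffold: 2 sides x n_bins
bin_scaffold <- function(max_dist = 100L, bin_width = 10L) {
  nb <- max_dist %/% bin_width
  data.frame(
    side = rep(c("u", "d"), each = nb),
    bin = rep(seq_len(nb), 2L),
    stringsAsFactors = FALSE)
}

# Count one indel region.  `st` is gene_site_table(aln); `elig` the
# per-column eligibility flags for this indel's block.
count_indel_region <- function(indel, st, elig, poly = NULL,
                               sample_size = NULL,
                               max_dist = 100L, bin_width = 10L) {
  cfg <- indel$configuration
  mel_specific <- cfg %in% MEL_SPECIFIC_CONFIGS
  cs <- indel$mel_codon_start; ce <- indel$mel_codon_end

  sites <- st$sites
  sites$eligible <- elig[sites$col + 1L]
  dd <- codon_distances(sites$codon_index, cs, ce, max_dist)
  sites$side <- dd$side; sites$dist <- dd$distance
  sites <- sites[!is.na(sites$dist) & sites$eligible, , drop = FALSE]

  acgt <- function(x) x %in% NUCS
  if (mel_specific) {
    use <- acgt(sites$mel) & acgt(sites$sec) & acgt(sites$ere) &
           sites$sec == sites$ere
  } else {
    use <- acgt(sites$mel) & acgt(sites$sec)
  }
  div <- sites[use, , drop = FALSE]
  div$mismatch <- div$mel != div$sec
  div$bin <- ceiling(div$dist / bin_width)
  key <- paste(div$side, div$bin)

  scaffold <- bin_scaffold(max_dist, bin_width)
  skey <- paste(scaffold$side, scaffold$bin)
  agg <- function(vals, sel) {
    v <- tapply(vals[sel], key[sel], sum)
    out <- rep(0, nrow(scaffold))
    out[match(names(v), skey)] <- as.numeric(v)
    out
  }
  nondeg <- div$degeneracy == "nondegenerate"
  fourfold <- div$degeneracy == "fourfold"
  scaffold$n_sites_nondeg <- agg(rep(1, nrow(div)), nondeg)
  scaffold$n_sites_fourfold <- agg(rep(1, nrow(div)), fourfold)
  scaffold$Dn_mis <- agg(as.numeric(div$mismatch), nondeg)
  scaffold$Ds_mis <- agg(as.numeric(div$mismatch), fourfold)

  # amino-acid substitutions per codon
  cod <- st$codons
  cdd <- codon_distances(cod$codon_index, cs, ce, max_dist)
  cod$side <- cdd$side; cod$dist <- cdd$distance
  # codon eligible iff all three nucleotide columns eligible
  cod_elig <- tapply(elig[st$sites$col + 1L], st$sites$codon_index, all)
  cod$eligible <- as.logical(cod_elig[as.character(cod$codon_index)])
  cod <- cod[!is.na(cod$dist) & cod$eligible, , drop = FALSE]
  if (mel_specific) {
    cuse <- !is.na(cod$mel_aa) & !is.na(cod$sec_aa) & !is.na(cod$ere_aa) &
            cod$sec_aa == cod$ere_aa
    w <- 1
  } else {
    cuse <- !is.na(cod$mel_aa) & !is.na(cod$sec_aa)
    w <- 0.5
  }
  ca <- cod[cuse, , drop = FALSE]
  ca$diff <- ca$mel_aa != ca$sec_aa
  ckey <- paste(ca$side, ceiling(ca$dist / bin_width))
  cagg <- function(vals) {
    v <- tapply(vals, ckey, sum)
    out <- rep(0, nrow(scaffold))
    out[match(names(v), skey)] <- as.numeric(v)
    out
  }
  scaffold$aa_sites <- cagg(rep(1, nrow(ca)))
  scaffold$aa_subs <- cagg(as.numeric(ca$diff)) * w
  scaffold$aa_subs_cons <- cagg(as.numeric(ca$diff & ca$conservative)) * w
  scaffold$cons_sites <- cagg(as.numeric(ca$conservative))

  # polymorphism: all eligible class sites are the denominator; a site is
  # polymorphic when biallelic with both alleles in >= 2 lines
  pn_all <- sites$degeneracy == "nondegenerate" & acgt(sites$mel)
  ps_all <- sites$degeneracy == "fourfold" & acgt(sites$mel)
  pkey <- paste(sites$side, ceiling(sites$dist / bin_width))
  pagg <- function(sel) {
    v <- tapply(rep(1, nrow(sites))[sel], pkey[sel], sum)
    out <- rep(0, nrow(scaffold))
    out[match(names(v), skey)] <- as.numeric(v)
    out
  }
  scaffold$poly_sites_nondeg <- pagg(pn_all)
  scaffold$poly_sites_fourfold <- pagg(ps_all)
  scaffold$Pn <- 0; scaffold$Ps <- 0; scaffold$n_multi_allelic <- 0L

  if (!is.null(poly) && nrow(poly) > 0L) {
    pg <- poly[poly$gene_id == indel$gene_id, , drop = FALSE]
    if (nrow(pg) > 0L) {
      pg$pos <- pg$codon_index * 3L + pg$codon_pos
      idx <- match(pg$pos, st$sites$pos)
      ok <- !is.na(idx)
      pg <- pg[ok, , drop = FALSE]; idx <- idx[ok]
      pg$col <- st$sites$col[idx]
      pg$degeneracy <- st$sites$degeneracy[idx]
      pdd <- codon_distances(pg$codon_index, cs, ce, max_dist)
      pg$side <- pdd$side; pg$dist <- pdd$distance
      pg$eligible <- elig[pg$col + 1L]
      pg <- pg[!is.na(pg$dist) & pg$eligible, , drop = FALSE]
      if (nrow(pg) > 0L) {
        counts <- as.matrix(pg[, c("A", "C", "G", "T")])
        n_all <- rowSums(counts > 0)
        missing_ok <- if (is.null(sample_size)) rep(TRUE, nrow(pg))
                      else passes_missingness(pg$n_called, sample_size)
        multi <- n_all > 2L
        minor2 <- apply(counts, 1L, function(x) {
          nz <- sort(x[x > 0], decreasing = TRUE)
          length(nz) == 2L && nz[2L] >= 2L
        })
        is_poly <- !multi & minor2 & missing_ok
        bkey <- paste(pg$side, ceiling(pg$dist / bin_width))
        add <- function(sel) {
          v <- tapply(rep(1, nrow(pg))[sel], bkey[sel], sum)
          out <- rep(0, nrow(scaffold))
          out[match(names(v), skey)] <- as.numeric(v)
          out
        }
        scaffold$Pn <- add(is_poly & pg$degeneracy == "nondegenerate")
        scaffold$Ps <- add(is_poly & pg$degeneracy == "fourfold")
        scaffold$n_multi_allelic <- sum(multi)
      }
    }
  }
  scaffold$gene_id <- indel$gene_id
  scaffold$configuration <- cfg
  scaffold
}

#' Count divergence and polymorphism around every kept indel
#'
#' For each kept indel in the catalog, classifies the surrounding sites
#' into distance bins (default: 10 bins of 10 codons each side) and counts,
#' per bin: non-degenerate and fourfold site totals with their mel-vs-sec
#' mismatches (restricted to sec==ere sites, weight 1, for configurations
#' a-b'; all sites for c-f'), amino-acid substitutions on the focal
#' terminal segment (halved for shared-branch configurations c-f'), the
#' subset at conservative sites, and polymorphism counts under the
#' both-alleles-in-at-least-two-lines rule.
#'
#' @param alignments Named list of [gene_alignment()] objects.
#' @param catalog An [classify_indels()] result.
#' @param poly A [polymorphism_table()] or `NULL`.
#' @param tree A [species_tree()].
#' @param window Clean-flank width in nucleotides (default 10).
#' @param max_dist Maximum distance in codons (default 100).
#' @param bin_width Bin width in codons (default 10).
#' @return Long data frame: one row per indel x side x bin, with an
#'   `indel_id` key.
#' @export
analyze_catalog <- function(alignments, catalog, poly = NULL,
                            tree = species_tree(), window = 10L,
                            max_dist = 100L, bin_width = 10L) {
  kept <- catalog[catalog$kept, , drop = FALSE]
  sample_size <- if (!is.null(poly)) attr(poly, "sample_size")
  if (!is.null(names(alignments))) {
    aln_by_gene <- alignments
  } else {
    aln_by_gene <- stats::setNames(alignments,
                                   vapply(alignments, `[[`, "", "gene_id"))
  }
  st_cache <- list()
  out <- vector("list", nrow(kept))
  for (i in seq_len(nrow(kept))) {
    indel <- kept[i, ]
    g <- indel$gene_id
    aln <- aln_by_gene[[g]]
    if (is.null(aln)) stop("no alignment for gene '", g, "'")
    if (is.null(st_cache[[g]])) st_cache[[g]] <- gene_site_table(aln, tree)
    elig <- eligibility_flags(aln, tree, indel$col_start, indel$col_end,
                              window)
    bb <- count_indel_region(indel, st_cache[[g]], elig, poly, sample_size,
                             max_dist, bin_width)
    bb$indel_id <- paste0(g, ":", indel$col_start)
    out[[i]] <- bb
  }
  if (length(out) == 0L) return(NULL)
  do.call(rbind, out)
}

#' McDonald-Kreitman alpha from pooled fractions
#'
#' `alpha = 1 - (Pn/Ps)/(Dn/Ds)`, the estimated proportion of
#' non-synonymous substitutions driven by positive selection.  All four
#' arguments are fractions (counts over site totals).
#'
#' @param Dn,Ds,Pn,Ps Divergence / polymorphism fractions.
#' @return Numeric alpha, or `NA_real_` when `Ps`, `Dn` or `Ds` is zero
#'   (or any is missing).
#' @export
#' @examples
#' mk_alpha(0.01, 0.01, 0.002, 0.008)  # 0.75
mk_alpha <- function(Dn, Ds, Pn, Ps) {
  if (anyNA(c(Dn, Ds, Pn, Ps))) return(NA_real_)
  if (Ps == 0 || Dn == 0 || Ds == 0) return(NA_real_)
  1 - (Pn / Ps) / (Dn / Ds)
}

# pooled MK components from a slice of the counts table
pool_counts <- function(counts) {
  with(counts, {
    Dn <- if (sum(n_sites_nondeg) > 0) sum(Dn_mis) / sum(n_sites_nondeg) else NA_real_
    Ds <- if (sum(n_sites_fourfold) > 0) sum(Ds_mis) / sum(n_sites_fourfold) else NA_real_
    Pn <- if (sum(poly_sites_nondeg) > 0) sum(Pn) / sum(poly_sites_nondeg) else NA_real_
    Ps <- if (sum(poly_sites_fourfold) > 0) sum(Ps) / sum(poly_sites_fourfold) else NA_real_
    list(Dn = Dn, Ds = Ds, Pn = Pn, Ps = Ps,
         Dn_mis = sum(Dn_mis), Ds_mis = sum(Ds_mis),
         alpha = mk_alpha(Dn, Ds, Pn, Ps))
  })
}

#' Pooled MK alpha over a counts slice, with bootstrap CI over indels
#'
#' Pools counts across indel regions (the aggregation used for the binned
#' alpha fractions), computes alpha, and attaches a percentile bootstrap
#' CI obtained by resampling whole indel regions.
#'
#' @param counts Slice of an [analyze_catalog()] table.
#' @param B Bootstrap trials (default 1000).
#' @param seed RNG seed.
#' @return List with the pooled components, `alpha`, and `ci95`.
#' @export
mk_alpha_pooled <- function(counts, B = 1000L, seed = 1L) {
  point <- pool_counts(counts)
  ids <- unique(counts$indel_id)
  if (length(ids) >= 2L) {
    groups <- split(seq_len(nrow(counts)), counts$indel_id)[ids]
    stats <- with_seed(seed, vapply(seq_len(B), function(b) {
      take <- sample.int(length(ids), length(ids), replace = TRUE)
      idx <- unlist(groups[take], use.names = FALSE)
      pool_counts(counts[idx, , drop = FALSE])$alpha
    }, numeric(1)))
    qs <- stats::quantile(stats, c(0.025, 0.975), names = FALSE, na.rm = TRUE)
  } else {
    qs <- c(NA_real_, NA_real_)
  }
  c(point, list(ci95 = qs, n_indels = length(ids)))
}

# per-indel x bin matrix of a column from the long counts table
indel_bin_matrix <- function(counts, value = "aa_subs",
                             max_dist = 100L, bin_width = 10L) {
  nb <- max_dist %/% bin_width
  keys <- c(paste0("u", seq_len(nb)), paste0("d", seq_len(nb)))
  ids <- unique(counts$indel_id)
  m <- matrix(0, nrow = length(ids), ncol = length(keys),
              dimnames = list(ids, keys))
  k <- paste0(counts$side, counts$bin)
  m[cbind(match(counts$indel_id, ids), match(k, keys))] <- counts[[value]]
  m
}

#' Adaptive walk length: case-minus-control excess substitutions
#'
#' Per-bin excess = mean amino-acid substitutions per case indel minus the
#' mean per control indel; the walk length is the sum over all 20 bins
#' (10 upstream, 10 downstream).  The 95% CI comes from bootstrapping the
#' case and control indel regions independently with replacement.
#'
#' @param case_counts,control_counts Slices of an [analyze_catalog()]
#'   table: the case configuration (indel in the focal lineage) and its
#'   mirror control.
#' @param B Bootstrap trials (default 1000).
#' @param seed RNG seed.
#' @param max_dist,bin_width Binning parameters (defaults 100, 10).
#' @return List with `per_bin` (named numeric vector of excesses),
#'   `total`, `ci95`, `n_case`, `n_control`; `NA` sentinels when either
#'   set is empty.
#' @export
walk_length <- function(case_counts, control_counts, B = 1000L, seed = 1L,
                        max_dist = 100L, bin_width = 10L,
                        return_draws = FALSE) {
  if (is.null(case_counts) || is.null(control_counts) ||
      nrow(case_counts) == 0L || nrow(control_counts) == 0L) {
    return(list(per_bin = NULL, total = NA_real_,
                ci95 = c(NA_real_, NA_real_), n_case = 0L, n_control = 0L))
  }
  mc <- indel_bin_matrix(case_counts, "aa_subs", max_dist, bin_width)
  mk <- indel_bin_matrix(control_counts, "aa_subs", max_dist, bin_width)
  per_bin <- colMeans(mc) - colMeans(mk)
  # the summed per-bin excess equals the difference of per-indel totals,
  # so the bootstrap resamples whole indel regions through their totals
  ci <- two_sample_mean_diff_ci(rowSums(mc), rowSums(mk), B = B,
                                seed = seed)
  out <- list(per_bin = per_bin, total = sum(per_bin), ci95 = ci$ci95,
              n_case = nrow(mc), n_control = nrow(mk), B = B)
  if (return_draws) out$draws <- ci$draws
  out
}

#' Bootstrap CI for a difference of means of two independent unit sets
#'
#' Percentile interval for `mean(case) - mean(control)` with both sides
#' resampled independently with replacement — the resampling scheme behind
#' the walk-length CI, where the units are indel regions.
#'
#' @param case,control Numeric vectors of per-unit values.
#' @param B Bootstrap trials.
#' @param seed RNG seed.
#' @param conf Confidence level (default 0.95).
#' @return List with `point`, `ci95`, `draws`.
#' @export
two_sample_mean_diff_ci <- function(case, control, B = 1000L, seed = 1L,
                                    conf = 0.95) {
  n1 <- length(case); n2 <- length(control)
  stopifnot(n1 >= 1L, n2 >= 1L)
  draws <- with_seed(seed, {
    m1 <- matrix(sample(case, n1 * B, replace = TRUE), nrow = B)
    m2 <- matrix(sample(control, n2 * B, replace = TRUE), nrow = B)
    rowMeans(m1) - rowMeans(m2)
  })
  a <- (1 - conf) / 2
  list(point = mean(case) - mean(control),
       ci95 = stats::quantile(draws, c(a, 1 - a), names = FALSE),
       draws = draws)
}

#' Aggregate per-configuration walk-length excesses
#'
#' The total walk length for an indel type is the sum of the
#' configuration-level case-minus-control excesses (e.g. the two deletion
#' components b-vs-b' and d-vs-d').
#'
#' @param components Numeric vector of configuration-level excesses.
#' @return Their sum.
#' @export
#' @examples
#' combine_walk_components(c(2.60, 2.17))  # 4.77
combine_walk_components <- function(components) {
  stopifnot(is.numeric(components), length(components) >= 1L)
  sum(components)
}

#' Contingency tables for the upstream/downstream and conservation contrasts
#'
#' Builds the 2x2 integer tables for Fisher's exact test: (i) amino-acid
#' substitutions in the nearest upstream bin versus the nearest downstream
#' bin, case versus control; (ii) substitutions at conservative versus
#' non-conservative sites, case versus control.  Fractional substitution
#' weights (from the halving rule for shared-branch configurations) are
#' summed first and then rounded to the nearest integer.
#'
#' @param case_counts,control_counts Slices of an [analyze_catalog()] table.
#' @return List with matrices `updown` (`rows = case/control`,
#'   `cols = upstream/downstream`) and `conservation`
#'   (`cols = conservative/other`).
#' @export
contingency_tables <- function(case_counts, control_counts) {
  first_bin <- function(x, s) sum(x$aa_subs[x$side == s & x$bin == 1L])
  updown <- matrix(round(c(
    first_bin(case_counts, "u"), first_bin(case_counts, "d"),
    first_bin(control_counts, "u"), first_bin(control_counts, "d"))),
    nrow = 2L, byrow = TRUE,
    dimnames = list(c("case", "control"), c("upstream", "downstream")))
  cons <- matrix(round(c(
    sum(case_counts$aa_subs_cons),
    sum(case_counts$aa_subs) - sum(case_counts$aa_subs_cons),
    sum(control_counts$aa_subs_cons),
    sum(control_counts$aa_subs) - sum(control_counts$aa_subs_cons))),
    nrow = 2L, byrow = TRUE,
    dimnames = list(c("case", "control"), c("conservative", "other")))
  list(updown = updown, conservation = cons)
}
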