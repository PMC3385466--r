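# Synthetic data: codon sequences evolved on the fixed tree, indel events
# placed on configuration-specific branches, a decaying post-indel burst of
# non-synonymous substitutions in the focal lineage(s), and neutral
# within-species polymorphism with derived counts proportional to 1/i.

# codon ids are 1..64 with id = 16*(n1-1) + 4*(n2-1) + n3 over A,C,G,T=1..4
.codon_env <- new.env(parent = emptyenv())

codon_tables <- function() {
  if (!is.null(.codon_env$aa)) return(.codon_env)
  code <- Biostrings::GENETIC_CODE
  nt_of <- function(ch) match(ch, NUCS)
  aa <- integer(64L)
  aa_letters <- sort(unique(code[code != "*"]))
  for (cd in names(code)) {
    id <- 16L * (nt_of(substr(cd, 1, 1)) - 1L) +
           4L * (nt_of(substr(cd, 2, 2)) - 1L) +
                 nt_of(substr(cd, 3, 3))
    aa[id] <- if (code[[cd]] == "*") 0L else match(code[[cd]], aa_letters)
  }
  .codon_env$aa <- aa                       # 0 = stop
  .codon_env$nonstop <- which(aa != 0L)
  .codon_env
}

# random non-stop codons as an integer nucleotide vector of length 3*k
random_codons <- function(k) {
  ct <- codon_tables()
  ids <- sample(ct$nonstop, k, replace = TRUE) - 1L
  as.integer(rbind(ids %/% 16L, (ids %/% 4L) %% 4L, ids %% 4L)) + 1L
}

codon_ids <- function(seq_int) {
  m <- matrix(seq_int, nrow = 3L)
  16L * (m[1, ] - 1L) + 4L * (m[2, ] - 1L) + m[3, ]
}

# Evolve an integer nucleotide sequence (codon-aligned) for branch length t,
# expressed as expected substitutions per fourfold (synonymous) site.
# Proposals are per-site Poisson(t) random nucleotide changes; synonymous
# proposals are always accepted, non-synonymous ones with probability
# omega, and changes creating stop codons are rejected.
evolve_branch <- function(seq_int, t, omega) {
  if (t <= 0) return(seq_int)
  ct <- codon_tables()
  nprop <- stats::rpois(length(seq_int), t)
  pending <- which(nprop > 0L)
  while (length(pending) > 0L) {
    cod_idx <- (pending - 1L) %/% 3L
    sel <- pending[!duplicated(cod_idx)]     # one proposal per codon per pass
    cur <- seq_int[sel]
    new <- ((cur - 1L + sample.int(3L, length(sel), replace = TRUE)) %% 4L) + 1L
    cidx <- (sel - 1L) %/% 3L
    base <- cidx * 3L
    c1 <- seq_int[base + 1L]; c2 <- seq_int[base + 2L]; c3 <- seq_int[base + 3L]
    pos <- sel - base
    n1 <- ifelse(pos == 1L, new, c1)
    n2 <- ifelse(pos == 2L, new, c2)
    n3 <- ifelse(pos == 3L, new, c3)
    old_id <- 16L * (c1 - 1L) + 4L * (c2 - 1L) + c3
    new_id <- 16L * (n1 - 1L) + 4L * (n2 - 1L) + n3
    aa_old <- ct$aa[old_id]; aa_new <- ct$aa[new_id]
    accept <- aa_new != 0L &
      (aa_new == aa_old | stats::runif(length(sel)) < omega)
    seq_int[sel[accept]] <- new[accept]
    nprop[sel] <- nprop[sel] - 1L
    pending <- pending[nprop[pending] > 0L]
  }
  seq_int
}

#' Simulation parameters
#'
#' Defaults define the study conditions the generator emulates: 500 genes
#' of 250 codons evolving on the fixed six-species topology with
#' Drosophila-scale branch lengths (mel-sec synonymous divergence 0.10),
#' dN/dS 0.15, one indel per gene drawn uniformly over the 12
#' configurations with a short length distribution, a post-indel burst of
#' `lambda_total` expected extra amino-acid substitutions per affected
#' lineage decaying geometrically with scale 25 codons and placed upstream
#' with probability 0.7 (twice as readily at conservative sites), half the
#' codon sites invariant among the basal species, per-fourfold-site SNP
#' density 0.01 with neutral 1/i derived counts in a panel of 162 lines,
#' and polymorphic indels whose spectra are singleton-enriched, more
#' strongly for deletions.
#'
#' @param n_genes,gene_length_codons Number and length of genes.
#' @param branch_lengths Named vector of expected synonymous substitutions
#'   per fourfold site on each edge.
#' @param omega dN/dS acceptance probability for non-synonymous changes.
#' @param indel_prob Probability a gene carries one indel.
#' @param config_probs Named weights over the 12 configurations.
#' @param length_probs Weights for indel lengths 1..5 codons.
#' @param lambda_total Expected excess amino-acid substitutions per
#'   affected lineage for case configurations a-d.
#' @param decay_scale Geometric decay scale of the excess, codons.
#' @param upstream_bias Probability an excess substitution falls
#'   N-terminal of the indel.
#' @param cons_weight Relative preference of excess substitutions for
#'   conservative sites.
#' @param cons_fraction Fraction of codon sites invariant among the six
#'   basal species.
#' @param theta Per-fourfold-site SNP probability.
#' @param sample_n Lines in the polymorphism panel.
#' @param indel_poly_rate Expected polymorphic indels per gene.
#' @param singleton_excess_ins,singleton_excess_del Multipliers on the
#'   singleton class of the 1/i spectrum for polymorphic insertions /
#'   deletions.
#' @param seed Mandatory RNG seed.
#' @return List of validated parameters (class `sim_params`).
#' @export
sim_params <- function(n_genes = 500L,
                       gene_length_codons = 250L,
                       branch_lengths = c(mel = 0.05, sec = 0.05,
                                          melsec = 0.05, ere = 0.10,
                                          melsecere = 0.10, ana = 0.30,
                                          melsecereana = 0.15, pse = 0.40,
                                          root_pse = 0.10, vir = 0.50),
                       omega = 0.15,
                       indel_prob = 1.0,
                       config_probs = NULL,
                       length_probs = c(0.55, 0.20, 0.10, 0.08, 0.07),
                       lambda_total = 2.5,
                       decay_scale = 25,
                       upstream_bias = 0.7,
                       cons_weight = 2,
                       cons_fraction = 0.5,
                       theta = 0.01,
                       sample_n = 162L,
                       indel_poly_rate = 0.3,
                       singleton_excess_ins = 3,
                       singleton_excess_del = 8,
                       seed) {
  if (missing(seed)) stop("a seed is mandatory")
  if (is.null(config_probs)) {
    config_probs <- stats::setNames(rep(1 / 12, 12), CONFIG_TABLE$configuration)
  }
  stopifnot(all(names(config_probs) %in% CONFIG_TABLE$configuration),
            all(branch_lengths >= 0), omega >= 0,
            upstream_bias >= 0, upstream_bias <= 1,
            lambda_total >= 0, cons_fraction >= 0, cons_fraction <= 1)
  margin <- 110L
  if (gene_length_codons < 2L * margin + 10L) {
    stop("gene_length_codons must be at least ", 2L * margin + 10L,
         " so that full 100-codon windows fit around an indel")
  }
  p <- as.list(environment())
  class(p) <- "sim_params"
  p
}

# map species-coordinate codons back to base coordinates given the indel
# interval [p0, p0 + shift) in that species (shift > 0: carried insertion;
# shift < 0 means a deletion of |shift| codons at p0)
base_codon_of <- function(codon, p0, shift) {
  ifelse(codon < p0, codon,
         ifelse(shift >= 0, codon - shift, codon + abs(shift)))
}

# one excess amino-acid substitution applied to seq at codon j (0-based);
# returns list(seq, pos, old, new)
apply_aa_substitution <- function(seq_int, j) {
  ct <- codon_tables()
  repeat {
    pos <- sample.int(3L, 1L)
    i <- 3L * j + pos
    old <- seq_int[i]
    new <- ((old - 1L + sample.int(3L, 1L)) %% 4L) + 1L
    trial <- seq_int
    trial[i] <- new
    id_old <- codon_ids(seq_int[(3L * j + 1L):(3L * j + 3L)])
    id_new <- codon_ids(trial[(3L * j + 1L):(3L * j + 3L)])
    if (ct$aa[id_new] != 0L && ct$aa[id_new] != ct$aa[id_old]) {
      return(list(seq = trial, pos = pos - 1L, old = old, new = new))
    }
  }
}

int_to_string <- function(seq_int) {
  paste(NUCS[seq_int], collapse = "")
}

# splice a gap block of len_nt '-' characters into a string at nt offset
splice_gaps <- function(s, at_nt, len_nt) {
  paste0(substr(s, 1L, at_nt), strrep("-", len_nt),
         substr(s, at_nt + 1L, nchar(s)))
}

#' Simulate a full dataset with a truth record
#'
#' Evolves codon sequences for the six focal species site-independently
#' along the fixed topology, places at most one indel per gene on the
#' branch implied by its drawn configuration, injects the post-indel
#' excess of amino-acid substitutions into the focal terminal lineage(s)
#' for case configurations a-d (both mel and sec for the shared-branch
#' configurations c,d), generates basal-species rows with a fixed fraction
#' of invariant codon sites, and draws neutral within-species SNP and
#' indel polymorphism.  Everything is reproducible from the seed.
#'
#' @param params A [sim_params()] object.
#' @return List with `alignments` (named list of [gene_alignment()]),
#'   `snps` ([polymorphism_table()]), `indel_poly`
#'   ([indel_polymorphism_table()]), and `truth` (list with data frames
#'   `indels` and `excess_events`, plus the parameters).
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(params$seed, simulate_dataset_impl(params))
}

simulate_dataset_impl <- function(p) {
  ct <- codon_tables()
  L <- p$gene_length_codons
  nt_per_gene <- 3L * L
  G <- p$n_genes
  bl <- p$branch_lengths

  # --- evolve the focal clade on the concatenated genes ---------------
  root <- random_codons(G * L)
  n5 <- evolve_branch(root, bl[["root_pse"]], p$omega)        # anc(mel..pse)
  n4 <- evolve_branch(n5, bl[["melsecereana"]], p$omega)      # anc(mel..ana)
  n3 <- evolve_branch(n4, bl[["melsecere"]], p$omega)         # anc(mel,sec,ere)
  n2 <- evolve_branch(n3, bl[["melsec"]], p$omega)            # anc(mel,sec)
  tip <- list(
    mel = evolve_branch(n2, bl[["mel"]], p$omega),
    sec = evolve_branch(n2, bl[["sec"]], p$omega),
    ere = evolve_branch(n3, bl[["ere"]], p$omega),
    ana = evolve_branch(n4, bl[["ana"]], p$omega)
  )

  # --- basal species (incl. pse, vir): conservation model -------------
  conserved <- stats::runif(G * L) < p$cons_fraction
  basal_names <- c("pse", "vir", "per", "wil", "moj", "gri")
  basal <- list()
  for (sp in basal_names) {
    s <- root
    nonc <- which(!conserved)
    if (length(nonc) > 0L) {
      repl <- random_codons(length(nonc))
      idx <- as.integer(rbind(3L * (nonc - 1L) + 1L,
                              3L * (nonc - 1L) + 2L,
                              3L * (nonc - 1L) + 3L))
      s[idx] <- repl
    }
    basal[[sp]] <- s
  }

  # --- indel assignment ------------------------------------------------
  cfg_names <- names(p$config_probs)
  has_indel <- stats::runif(G) < p$indel_prob
  cfg_draw <- sample(cfg_names, G, replace = TRUE,
                     prob = unname(p$config_probs))
  len_draw <- sample.int(length(p$length_probs), G, replace = TRUE,
                         prob = p$length_probs)
  margin <- p$margin
  pos_draw <- margin +
    floor(stats::runif(G) * (L - 2L * margin - len_draw + 1L))

  species10 <- c("mel", "sec", "ere", "ana", basal_names)
  alignments <- vector("list", G)
  indel_rows <- list()
  event_rows <- list()
  snp_rows <- list()
  ipoly_rows <- list()

  # carriers of the indel material change per configuration
  subtree <- list(mel = "mel", sec = "sec", ere = "ere", ana = "ana",
                  melsec = c("mel", "sec"),
                  melsecere = c("mel", "sec", "ere"))

  for (g in seq_len(G)) {
    gene_id <- sprintf("g%04d", g)
    rng <- ((g - 1L) * nt_per_gene + 1L):(g * nt_per_gene)
    seqs <- lapply(tip, function(s) s[rng])
    for (sp in basal_names) seqs[[sp]] <- basal[[sp]][rng]
    cons_g <- conserved[((g - 1L) * L + 1L):(g * L)]

    cfg <- NA_character_; type <- NA_character_
    p0 <- NA_integer_; li <- NA_integer_
    ins_nt <- NULL
    if (has_indel[g]) {
      cfg <- cfg_draw[g]
      crow <- CONFIG_TABLE[CONFIG_TABLE$configuration == cfg, ]
      type <- crow$type
      li <- len_draw[g]
      p0 <- pos_draw[g]
      carriers_evt <- subtree[[crow$branch]]
      if (type == "insertion") {
        ins_nt <- random_codons(li)
        for (sp in carriers_evt) {
          s <- seqs[[sp]]
          seqs[[sp]] <- c(s[seq_len(3L * p0)], ins_nt,
                          s[(3L * p0 + 1L):length(s)])
        }
      } else {
        drop_idx <- (3L * p0 + 1L):(3L * p0 + 3L * li)
        for (sp in carriers_evt) seqs[[sp]] <- seqs[[sp]][-drop_idx]
      }

      # --- excess walk on the focal terminal lineage(s) ----------------
      targets <- switch(cfg,
                        "a" = "mel", "b" = "mel",
                        "c" = c("mel", "sec"), "d" = c("mel", "sec"),
                        character(0))
      # each excess event is one extra OBSERVABLE amino-acid substitution:
      # it is placed at a codon where mel and sec currently agree (and,
      # for the mel-specific configurations a/b, where sec agrees with
      # ere), so lambda_total is the expected extra amino-acid
      # substitution count the estimator measures
      ct <- codon_tables()
      aa_at <- function(s, j) ct$aa[codon_ids(s[(3L * j + 1L):(3L * j + 3L)])]
      for (lineage in targets) {
        shift <- if (type == "insertion" && lineage %in% carriers_evt) li
                 else if (type == "deletion" && lineage %in% carriers_evt) -li
                 else 0L
        iv_start <- p0
        iv_end <- p0 + max(shift, 0L)
        n_ev <- stats::rpois(1L, p$lambda_total)
        for (e in seq_len(n_ev)) {
          placeable <- FALSE
          for (try in seq_len(200L)) {
            up <- stats::runif(1) < p$upstream_bias
            repeat {
              d <- 1L + stats::rgeom(1L, 1 / p$decay_scale)
              if (d <= margin - 5L) break
            }
            j <- if (up) iv_start - d else iv_end + d - 1L
            bj <- base_codon_of(j, p0, shift)
            # sec shares mel's coordinate shift only for the shared-branch
            # configurations c/d; for a/b it sits in base coordinates
            j_sec <- if (cfg %in% c("c", "d")) j else bj
            agree <- aa_at(seqs$mel, j) == aa_at(seqs$sec, j_sec)
            if (cfg %in% c("a", "b")) {
              agree <- agree && aa_at(seqs$sec, j_sec) == aa_at(seqs$ere, bj)
            }
            if (!agree) next
            is_cons <- cons_g[bj + 1L]
            if (is_cons || stats::runif(1) < 1 / p$cons_weight) {
              placeable <- TRUE
              break
            }
          }
          if (!placeable) next
          res <- apply_aa_substitution(seqs[[lineage]], j)
          seqs[[lineage]] <- res$seq
          event_rows[[length(event_rows) + 1L]] <- data.frame(
            gene_id = gene_id, configuration = cfg, lineage = lineage,
            side = if (up) "u" else "d", distance = d, codon = j,
            base_codon = bj, conservative = is_cons,
            nt_pos = res$pos, stringsAsFactors = FALSE)
        }
      }
      indel_rows[[length(indel_rows) + 1L]] <- data.frame(
        gene_id = gene_id, configuration = cfg, type = type,
        length_codons = li, position = p0, stringsAsFactors = FALSE)
    }

    # --- alignment assembly -------------------------------------------
    rows <- character(length(species10))
    names(rows) <- species10
    if (has_indel[g] && type == "insertion") {
      carriers_evt <- subtree[[CONFIG_TABLE$branch[
        CONFIG_TABLE$configuration == cfg]]]
      for (sp in species10) {
        if (sp %in% carriers_evt) {
          rows[[sp]] <- int_to_string(seqs[[sp]])
        } else {
          rows[[sp]] <- splice_gaps(int_to_string(seqs[[sp]]),
                                    3L * p0, 3L * li)
        }
      }
    } else if (has_indel[g] && type == "deletion") {
      carriers_evt <- subtree[[CONFIG_TABLE$branch[
        CONFIG_TABLE$configuration == cfg]]]
      for (sp in species10) {
        if (sp %in% carriers_evt) {
          rows[[sp]] <- splice_gaps(int_to_string(seqs[[sp]]),
                                    3L * p0, 3L * li)
        } else {
          rows[[sp]] <- int_to_string(seqs[[sp]])
        }
      }
    } else {
      for (sp in species10) rows[[sp]] <- int_to_string(seqs[[sp]])
    }
    alignments[[g]] <- gene_alignment(gene_id, rows)

    # --- SNP polymorphism on the final mel sequence --------------------
    mel_seq <- seqs$mel
    n_cod_mel <- length(mel_seq) %/% 3L
    cods <- NUCS[mel_seq]
    cod_str <- paste0(cods[seq(1L, 3L * n_cod_mel, by = 3L)],
                      cods[seq(2L, 3L * n_cod_mel, by = 3L)],
                      cods[seq(3L, 3L * n_cod_mel, by = 3L)])
    for (cp in 0:2) {
      deg <- codon_site_degeneracy(cod_str, cp)
      pr <- ifelse(deg == "fourfold", p$theta,
                   ifelse(deg == "nondegenerate", p$theta * p$omega, 0))
      hit <- which(stats::runif(n_cod_mel) < pr)
      for (ci in hit) {
        pos_nt <- 3L * (ci - 1L) + cp + 1L
        anc <- mel_seq[pos_nt]
        der <- derived_allele(mel_seq, pos_nt, deg[ci])
        if (is.na(der)) next
        i_count <- sample_one_over_i(p$sample_n, 1L)
        cnt <- c(A = 0L, C = 0L, G = 0L, T = 0L)
        cnt[NUCS[anc]] <- p$sample_n - i_count
        cnt[NUCS[der]] <- i_count
        snp_rows[[length(snp_rows) + 1L]] <- data.frame(
          gene_id = gene_id, codon_index = ci - 1L, codon_pos = cp,
          A = cnt[["A"]], C = cnt[["C"]], G = cnt[["G"]], T = cnt[["T"]],
          n_called = p$sample_n, stringsAsFactors = FALSE)
      }
    }

    # --- polymorphic indels -------------------------------------------
    n_ip <- stats::rpois(1L, p$indel_poly_rate)
    for (k in seq_len(n_ip)) {
      it <- sample(c("insertion", "deletion"), 1L)
      w <- 1 / seq_len(p$sample_n - 1L)
      w[1L] <- w[1L] * if (it == "insertion") p$singleton_excess_ins
                       else p$singleton_excess_del
      dc <- sample.int(p$sample_n - 1L, 1L, prob = w)
      ipoly_rows[[length(ipoly_rows) + 1L]] <- data.frame(
        gene_id = gene_id,
        position = sample.int(n_cod_mel, 1L) - 1L,
        length_codons = 1L, type = it,
        derived_count = dc, n_called = p$sample_n,
        stringsAsFactors = FALSE)
    }
  }

  names(alignments) <- vapply(alignments, `[[`, "", "gene_id")
  snps <- if (length(snp_rows))
    polymorphism_table(do.call(rbind, snp_rows), p$sample_n) else NULL
  ipoly <- if (length(ipoly_rows))
    indel_polymorphism_table(do.call(rbind, ipoly_rows), p$sample_n) else NULL
  truth <- list(
    indels = if (length(indel_rows)) do.call(rbind, indel_rows) else NULL,
    excess_events = if (length(event_rows)) do.call(rbind, event_rows)
                    else NULL,
    params = p)
  list(alignments = alignments, snps = snps, indel_poly = ipoly,
       truth = truth)
}

# derived allele for a SNP at nt position pos_nt (1-based) given the site's
# degeneracy class: synonymous change at fourfold sites (any alternative),
# amino-acid-changing non-stop alternative at nondegenerate sites
derived_allele <- function(seq_int, pos_nt, deg) {
  ct <- codon_tables()
  j <- (pos_nt - 1L) %/% 3L
  cod <- seq_int[(3L * j + 1L):(3L * j + 3L)]
  alts <- setdiff(1:4, seq_int[pos_nt])
  alts <- sample(alts, length(alts))
  for (a in alts) {
    trial <- cod
    trial[pos_nt - 3L * j] <- a
    if (ct$aa[codon_ids(trial)] != 0L) return(a)
  }
  NA_integer_
}

# draw k derived counts with probability proportional to 1/i, i = 1..n-1
sample_one_over_i <- function(n, k) {
  i <- seq_len(n - 1L)
  sample.int(n - 1L, k, replace = TRUE, prob = 1 / i)
}

#' Simulate a neutral polymorphic-indel table
#'
#' Derived counts are drawn with probability proportional to `1/i` over
#' `i = 1..n-1`, the neutral infinite-sites expectation.
#'
#' @param n Sample size (>= 2).
#' @param S Number of variants (>= 1).
#' @param seed RNG seed.
#' @param type Indel type label for the records (default `"insertion"`).
#' @return An [indel_polymorphism_table()] with `S` records.
#' @export
simulate_neutral_indel_sfs <- function(n, S, seed, type = "insertion") {
  stopifnot(n >= 2L, S >= 1L)
  counts <- with_seed(seed, sample_one_over_i(n, S))
  indel_polymorphism_table(data.frame(
    gene_id = sprintf("sim%06d", seq_len(S)),
    position = 0L, length_codons = 1L, type = type,
    derived_count = counts, n_called = n,
    stringsAsFactors = FALSE), n)
}

#' Expected recoverable walk length from a truth record
#'
#' Sums, per case indel, the counting weight of its injected excess
#' substitutions (weight 1 for configurations a,b; 0.5 per lineage for the
#' shared-branch configurations c,d, whose amino-acid counts the estimator
#' halves), restricted to distances within `max_dist`; returns the mean
#' over case indels of the requested configurations.
#'
#' @param truth The `truth` element of [simulate_dataset()].
#' @param configs Case configurations to include (default `c("a","b","c","d")`).
#' @param max_dist Maximum distance (default 100 codons).
#' @return Mean counted excess per case indel.
#' @export
truth_walk_expectation <- function(truth, configs = c("a", "b", "c", "d"),
                                   max_dist = 100L) {
  ind <- truth$indels
  ind <- ind[ind$configuration %in% configs, , drop = FALSE]
  if (is.null(ind) || nrow(ind) == 0L) return(NA_real_)
  ev <- truth$excess_events
  if (is.null(ev)) return(0)
  ev <- ev[ev$configuration %in% configs & ev$distance <= max_dist, ,
           drop = FALSE]
  w <- ifelse(ev$configuration %in% c("c", "d"), 0.5, 1)
  sum(w) / nrow(ind)
}
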