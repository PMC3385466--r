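# End-to-end orchestration: simulate or read inputs, build the indel
# catalog, count divergence/polymorphism per distance bin, estimate MK
# alpha and walk lengths, summarize indel polymorphism, and emit tables.

CASE_CONTROL_PAIRS <- list(c("a", "a'"), c("b", "b'"), c("c", "c'"),
                           c("d", "d'"), c("e", "e'"), c("f", "f'"))

#' Assemble a run configuration
#'
#' Defaults reproduce the analysis parameters: 10-nt clean flanks, bins of
#' 10 codons out to 100 codons each side, and 1000 bootstrap trials.
#'
#' @param simulate A [sim_params()] object, or `NULL` to read inputs.
#' @param alignment_dir,snp_path,indel_path Input paths (used when
#'   `simulate` is `NULL`).
#' @param window Clean-flank width, nucleotides.
#' @param bin_width Bin width, codons.
#' @param max_dist Maximum distance, codons.
#' @param B Bootstrap trials.
#' @param seed RNG seed for all stochastic steps of the analysis.
#' @param out_dir Output directory for TSV/JSON reports, or `NULL`.
#' @return List of class `run_config`.
#' @export
run_config <- function(simulate = NULL, alignment_dir = NULL,
                       snp_path = NULL, indel_path = NULL,
                       window = 10L, bin_width = 10L, max_dist = 100L,
                       B = 1000L, seed = 1L, out_dir = NULL) {
  if (is.null(simulate) && is.null(alignment_dir)) {
    stop("either a simulate block or an alignment directory is required")
  }
  structure(list(simulate = simulate, alignment_dir = alignment_dir,
                 snp_path = snp_path, indel_path = indel_path,
                 window = as.integer(window),
                 bin_width = as.integer(bin_width),
                 max_dist = as.integer(max_dist),
                 B = as.integer(B), seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Run the full analysis
#'
#' Stages: (i) indel catalog with the length-by-configuration matrix;
#' (ii) per-configuration distance-binned divergence/polymorphism with
#' pooled MK alpha and conservative fractions; (iii) walk-length estimates
#' for insertions (a-a' plus c-c'), deletions (b-b' plus d-d') and the
#' ancient-indel contrast (e-e' plus f-f'); (iv) the polymorphic-indel SFS
#' with its neutral expectation and Tajima's D; (v) Spearman distance
#' tests and Fisher contrasts; (vi) a machine-readable summary.  Filter
#' accounting (candidates in = kept + rejected by reason) is asserted.
#'
#' @param config A [run_config()].
#' @return List with elements `catalog`, `length_table`, `counts`,
#'   `mk_binned`, `mk_by_config`, `walk`, `sfs`, `spearman`, `fisher`,
#'   `filter_counts`, `config`; written as TSV/JSON when `out_dir` is set.
#' @export
run_full_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  tree <- species_tree()

  if (!is.null(config$simulate)) {
    ds <- simulate_dataset(config$simulate)
    alignments <- ds$alignments
    snps <- ds$snps
    ipoly <- ds$indel_poly
    truth <- ds$truth
  } else {
    alignments <- read_alignments(config$alignment_dir, tree)
    tabs <- read_polymorphism(config$snp_path, config$indel_path)
    snps <- tabs$snps
    ipoly <- tabs$indels
    truth <- NULL
  }

  catalog <- classify_indels(alignments, tree, config$window)
  filter_counts <- c(total = nrow(catalog), kept = sum(catalog$kept))
  rej <- table(catalog$reason[!catalog$kept])
  filter_counts <- c(filter_counts, stats::setNames(as.integer(rej),
                                                    names(rej)))
  stopifnot(filter_counts[["total"]] ==
            filter_counts[["kept"]] + sum(rej))
  message("indel candidates: ", filter_counts[["total"]],
          "; kept: ", filter_counts[["kept"]],
          if (length(rej)) paste0("; rejected: ",
            paste(names(rej), as.integer(rej), sep = "=", collapse = ", ")))

  counts <- analyze_catalog(alignments, catalog, snps, tree,
                            config$window, config$max_dist,
                            config$bin_width)

  # per-configuration x side x bin table with pooled fractions
  mk_binned <- NULL
  mk_by_config <- list()
  if (!is.null(counts)) {
    key <- interaction(counts$configuration, counts$side, counts$bin,
                       drop = TRUE)
    mk_binned <- do.call(rbind, lapply(split(counts, key), function(sl) {
      pc <- pool_counts(sl)
      data.frame(configuration = sl$configuration[1L], side = sl$side[1L],
                 bin = sl$bin[1L],
                 dist_lo = (sl$bin[1L] - 1L) * config$bin_width + 1L,
                 dist_hi = sl$bin[1L] * config$bin_width,
                 n_indels = length(unique(sl$indel_id)),
                 n_sites_nondeg = sum(sl$n_sites_nondeg),
                 n_sites_fourfold = sum(sl$n_sites_fourfold),
                 Dn = pc$Dn, Ds = pc$Ds, Pn = pc$Pn, Ps = pc$Ps,
                 aa_subs = sum(sl$aa_subs),
                 aa_rate = if (sum(sl$aa_sites) > 0)
                   sum(sl$aa_subs) / sum(sl$aa_sites) else NA_real_,
                 cons_fraction = if (sum(sl$aa_subs) > 0)
                   sum(sl$aa_subs_cons) / sum(sl$aa_subs) else NA_real_,
                 alpha = pc$alpha,
                 stringsAsFactors = FALSE)
    }))
    rownames(mk_binned) <- NULL
    mk_binned <- mk_binned[order(mk_binned$configuration, mk_binned$side,
                                 mk_binned$bin), ]
    for (cfg in unique(counts$configuration)) {
      mk_by_config[[cfg]] <- mk_alpha_pooled(
        counts[counts$configuration == cfg, ], B = config$B,
        seed = config$seed + 11L)
    }
  }

  # walk lengths per case/control pair, combined per indel type
  walk <- list(pairs = list())
  pair_totals <- list()
  for (k in seq_along(CASE_CONTROL_PAIRS)) {
    pr <- CASE_CONTROL_PAIRS[[k]]
    if (is.null(counts)) break
    wl <- walk_length(counts[counts$configuration == pr[1L], ],
                      counts[counts$configuration == pr[2L], ],
                      B = config$B, seed = config$seed + k,
                      max_dist = config$max_dist,
                      bin_width = config$bin_width, return_draws = TRUE)
    walk$pairs[[paste(pr, collapse = "_vs_")]] <- wl
    pair_totals[[pr[1L]]] <- wl
  }
  combine <- function(cfgs) {
    comps <- pair_totals[cfgs]
    comps <- comps[!vapply(comps, is.null, TRUE)]
    comps <- comps[vapply(comps, function(w) !is.na(w$total), TRUE)]
    if (length(comps) == 0L) return(list(total = NA_real_,
                                         ci95 = c(NA_real_, NA_real_)))
    total <- combine_walk_components(vapply(comps, `[[`, 0, "total"))
    with_draws <- comps[vapply(comps, function(w) !is.null(w$draws), TRUE)]
    if (length(with_draws) == length(comps)) {
      draws <- Reduce(`+`, lapply(comps, `[[`, "draws"))
      ci <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
    } else ci <- c(NA_real_, NA_real_)
    list(total = total, ci95 = ci,
         components = vapply(comps, `[[`, 0, "total"))
  }
  walk$insertions <- combine(c("a", "c"))
  walk$deletions <- combine(c("b", "d"))
  walk$ancient <- combine(c("e", "f"))

  # polymorphic-indel SFS
  sfs <- NULL
  if (!is.null(ipoly)) {
    sfs_ins <- indel_sfs(ipoly, type = "insertion")
    sfs_del <- indel_sfs(ipoly, type = "deletion")
    n <- attr(ipoly, "sample_size")
    sfs <- list(
      insertions = list(mean_freq = sfs_ins$mean_freq,
                        tajimas_d = tajimas_d(sfs_ins),
                        n_records = sfs_ins$n_records),
      deletions = list(mean_freq = sfs_del$mean_freq,
                       tajimas_d = tajimas_d(sfs_del),
                       n_records = sfs_del$n_records),
      neutral_mean_freq = neutral_expected_sfs(n)$mean_freq,
      binned = sfs_binned(ipoly))
  }

  # Spearman distance tests: substitutions per amino-acid site by distance
  spearman_tests <- list()
  if (!is.null(counts)) {
    for (cfg in sort(unique(counts$configuration))) {
      sl <- counts[counts$configuration == cfg, ]
      rate <- vapply(seq_len(config$max_dist %/% config$bin_width),
        function(b) {
          s <- sl[sl$bin == b, ]
          if (sum(s$aa_sites) > 0) sum(s$aa_subs) / sum(s$aa_sites)
          else NA_real_
        }, numeric(1))
      mids <- (seq_along(rate) - 0.5) * config$bin_width
      ok <- !is.na(rate)
      if (sum(ok) >= 3L && stats::sd(rate[ok]) > 0) {
        spearman_tests[[cfg]] <- spearman(mids[ok], rate[ok])
      }
    }
  }

  # Fisher contrasts
  fisher_tests <- list()
  if (!is.null(counts)) {
    for (pr in CASE_CONTROL_PAIRS) {
      cs <- counts[counts$configuration == pr[1L], ]
      ct <- counts[counts$configuration == pr[2L], ]
      if (nrow(cs) == 0L || nrow(ct) == 0L) next
      tabs <- contingency_tables(cs, ct)
      fisher_tests[[pr[1L]]] <- list(
        updown = c(fisher_exact(tabs$updown), list(table = tabs$updown)),
        conservation = c(fisher_exact(tabs$conservation),
                         list(table = tabs$conservation)))
    }
  }

  res <- list(catalog = catalog,
              length_table = catalog_length_table(catalog),
              counts = counts, mk_binned = mk_binned,
              mk_by_config = mk_by_config,
              walk = walk, sfs = sfs, spearman = spearman_tests,
              fisher = fisher_tests,
              filter_counts = as.list(filter_counts),
              truth = truth,
              config = config[setdiff(names(config), "out_dir")])

  if (!is.null(config$out_dir)) write_report_bundle(res, config$out_dir)
  res
}

# write the TSV/JSON report bundle
write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_indel_catalog(res$catalog, file.path(out_dir, "indel_catalog.tsv"))
  utils::write.table(res$length_table,
                     file.path(out_dir, "length_by_configuration.tsv"),
                     sep = "\t", quote = FALSE, col.names = NA)
  if (!is.null(res$mk_binned)) {
    utils::write.table(res$mk_binned, file.path(out_dir, "mk_binned.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(res$sfs)) {
    utils::write.table(res$sfs$binned, file.path(out_dir, "sfs_binned.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- list(
    parameters = res$config[c("window", "bin_width", "max_dist", "B",
                              "seed")],
    filter_counts = res$filter_counts,
    walk = list(
      insertions = res$walk$insertions[c("total", "ci95", "components")],
      deletions = res$walk$deletions[c("total", "ci95", "components")],
      ancient = res$walk$ancient[c("total", "ci95", "components")]),
    alpha_by_config = lapply(res$mk_by_config, function(a)
      a[c("alpha", "Dn", "Ds", "Pn", "Ps", "ci95", "n_indels")]),
    sfs = if (!is.null(res$sfs))
      res$sfs[c("insertions", "deletions", "neutral_mean_freq")],
    spearman = res$spearman,
    fisher = lapply(res$fisher, function(f) list(
      updown = f$updown[c("odds_ratio", "p")],
      conservation = f$conservation[c("odds_ratio", "p")]))
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(out_dir)
}
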