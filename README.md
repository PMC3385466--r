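# indelwalk

Frame-preserving insertions and deletions (indels) are large leaps in a
protein's sequence space.  If such a leap lands on the slope of a fitness
peak, positive selection should drag the sequence uphill through a series
of amino-acid substitutions — an adaptive walk — clustered near the indel
and concentrated soon after it.  `indelwalk` is an R package for
measuring these walks in *Drosophila*-style comparative data: it
polarizes indels on the fixed six-species phylogeny
`(((((mel,sec),ere),ana),pse),vir)` by Dollo parsimony with concordant
outgroups, counts synonymous and non-synonymous divergence and
polymorphism in 10-codon bins out to 100 codons on each side of every
indel, and contrasts indels that occurred in the *D. melanogaster*
lineage ("case") with their mirror images in the sister lineage
("control").

It is aimed at molecular-evolution researchers who want the full
pipeline — polarization, filtering, site classification, counting,
inference — runnable and testable on synthetic data with a known truth
record.

## The statistics at its core

* **McDonald–Kreitman α.**  With divergence fractions Dn, Ds (mismatch
  proportions at non-degenerate and fourfold-degenerate sites) and
  polymorphism fractions Pn, Ps (sites biallelic with both alleles in ≥ 2
  lines),

      α = 1 − (Pn/Ps) / (Dn/Ds)

  estimates the proportion of amino-acid substitutions fixed by positive
  selection.
* **Walk length.**  For each case/control configuration pair, the excess
  is the per-bin difference in mean amino-acid substitutions per indel,
  summed over all 20 bins; per-type totals add the configuration-level
  components (e.g. deletions: the b-vs-b′ and d-vs-d′ excesses).
  Substitution counts for shared-branch configurations are halved, since
  both the mel and sec lineages traversed the post-indel branch.
* **Indel site-frequency spectrum.**  Polarized polymorphic indels are
  compared with the neutral infinite-sites expectation (counts ∝ 1/i;
  mean derived frequency ((n−1)/n)/H(n−1) ≈ 0.175 at n = 162) and
  summarized by Tajima's D.
* **Uncertainty.**  Percentile bootstrap (default 1000 trials) over whole
  indel regions; Spearman rank tests for distance decay (exact
  permutation p for short vectors); Fisher's exact test (sample odds
  ratio, minimum-likelihood two-sided p) for upstream/downstream and
  conservation contrasts.

## Worked example

The `analysis/` scripts run the whole study on synthetic data.  Step 1
simulates 300 genes under the default conditions (one indel per gene over
the 12 configurations, a post-indel burst of 2.5 expected extra
substitutions per affected lineage, decaying with distance and biased
upstream) and writes alignments plus polymorphism tables; steps 2–4 read
only those files:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_catalog_indels.R
Rscript analysis/03_mk_walk.R
Rscript analysis/04_popgen_sfs.R
```

Step 2 reports the catalog (`candidates: 300; kept: 300`, with the
length-by-configuration table) and confirms `polarization recovery vs
truth: 100% of 300 indels`.  Step 3 prints, for this seed:

```
a vs a': excess 2.11  [1.18, 3.06]  (36 case / 28 control)
b vs b': excess 2.25  [1.11, 3.22]  (25 case / 22 control)
c vs c': excess 2.21  [1.17, 3.33]  (20 case / 25 control)
d vs d': excess 2.39  [1.59, 3.23]  (25 case / 19 control)
e vs e': excess -0.76  [-1.40, -0.17]  (23 case / 27 control)
f vs f': excess 0.54  [-0.09, 1.16]  (23 case / 27 control)
insertion walk length (a-a' + c-c'): 4.32
deletion  walk length (b-b' + d-d'): 4.64
```

Each recent configuration (a–d) recovers the injected per-lineage excess
of 2.5 within its bootstrap CI, the per-type totals combine the two
components, and the ancient e/f contrasts scatter around zero — ancient
indels trigger nothing in the terminal segment, by construction here and
as the method expects.  Step 4 prints:

```
insertions: 48 records, mean derived frequency 0.119, D = -0.91
deletions: 39 records, mean derived frequency 0.066, D = -1.60
neutral expectation at n = 162: mean frequency 0.176
```

showing the injected singleton excess (stronger for deletions) as mean
frequencies below the neutral 0.176 and negative Tajima's D.  Tables land
in `results/` (`indel_catalog.tsv`, `length_by_configuration.tsv`,
`mk_binned.tsv`, `mk_walk.json`, `sfs_binned.tsv`, `sfs_summary.json`).

The same pipeline runs in one call (and accepts real alignment/
polymorphism files in place of the simulate block):

```r
library(indelwalk)
res <- run_full_analysis(run_config(
  simulate = sim_params(n_genes = 300L, seed = 1L),
  B = 1000L, seed = 1L, out_dir = "results/run"))
res$walk$deletions$total      # deletion walk length with ci95
```

## Layout

```
R/                  package code: seqdata, indel_catalog, site_classes,
                    mk_walk, popgen_stats, resampling_stats,
                    synthetic_data, pipeline
analysis/           numbered workflow scripts (simulate -> catalog ->
                    MK/walk -> SFS), writing to results/
scripts/acceptance.R
tests/testthat/     unit, property and end-to-end recovery tests
vignettes/          methods vignette: model, conventions, generator scope
```
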