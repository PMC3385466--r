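---
title: "Measuring indel-triggered adaptive walks in protein-coding genes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring indel-triggered adaptive walks in protein-coding genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(indelwalk)
```

## The question and the design

A frame-preserving insertion or deletion (indel) moves a protein a long
way in sequence space.  If the new sequence sits on the slope of a fitness
peak rather than on its top, selection should drive a succession of
amino-acid substitutions — an adaptive walk — concentrated near the indel
and soon after it.  `indelwalk` measures that walk on a fixed six-species
Drosophila phylogeny, `(((((mel,sec),ere),ana),pse),vir)`, by a
case-control contrast: indels that occurred in the lineage leading to
*D. melanogaster* ("case") versus the mirror-image indels in the sister
lineage at the same phylogenetic depth ("control").  Substitutions in the
terminal *D. melanogaster* segment can have been triggered by the indel
only in the case sample, so the case-minus-control excess, as a function
of distance from the indel, is the walk.

Three depths are distinguished, each with an insertion and a deletion
variant and its mirrored control: after the mel–sec split (configurations
`a`/`a'` for insertions, `b`/`b'` for deletions), between the ere and
mel–sec splits (`c`/`c'`, `d`/`d'`), and between the ana and ere splits
(`e`/`e'`, `f`/`f'`).

## Polarization and filtering

Candidate indels are maximal runs of alignment columns with a constant
presence/absence pattern over the six focal species.  A pattern is
accepted only when a single Dollo-parsimony gain or loss event on one of
the six branches depicted by the configurations explains it, and both
outgroups (*D. pseudoobscura*, *D. virilis*) agree on the ancestral state:
both present means absences are deletions, both absent means presences
are insertions.  Exactly 12 of the 64 possible patterns qualify; the rest
(multiple events, discordant outgroups, or single events above the
*D. ananassae* split, which none of the configurations depicts) are
rejected.  The test suite verifies the 12/64 partition against an
exhaustive enumeration.

Kept indels must further be frame-preserving (exonic gap length a
multiple of 3; where a gap spans an exon border only the exonic part
counts) and must show 10 alignment columns of pure `A/C/G/T` on each side
in all six species.  The clean-flank window doubles as the guard against
coincident or overlapping indels from different clades, since any second
gap within the window dirties a flank.  The window length is a parameter
(`window`, default 10 nt); moderately shorter or longer windows change
little because the rule mostly removes poorly aligned regions.

Two conventions required a choice the data model does not dictate:

* **Junction coordinate.**  When the focal species lacks the material
  (deletions in its clade, insertions in the sister clade), the indel is
  anchored at the focal codon immediately C-terminal of the gap and has
  zero width; when the focal species carries the material, the indel
  occupies the codons overlapping the gap block.  Distances are then
  measured in codons from the nearest indel edge (the adjacent codon has
  distance 1), which is well defined for both geometries; indel-internal
  codons enter no count.
* **Error bound.**  Frameshifting indels are counted, not analysed; the
  ratio of coding frameshifts to non-multiple-of-three indels in short
  introns (`frameshift_error_bound()`) bounds the call error rate from
  above, because genuine coding frameshifts are removed by selection.

## Site classes

Degeneracy is assessed on the focal-species codon under the standard
genetic code: a position is *non-degenerate* when all three alternative
nucleotides change the amino acid (these are the non-synonymous sites)
and *fourfold* when none does (the synonymous sites); everything else is
excluded from both counts.  Positions where any substitution would create
a stop codon are excluded as well ("other"), avoiding nonsense changes
whose fate a polymorphism/divergence contrast cannot treat as ordinary
amino-acid replacement; this removes, e.g., the third position of TGG and
the AGA/CGA first positions from the non-degenerate class.  The full
64×3 table is checked against brute-force enumeration with an independent
translation routine.

A codon site is *conservative* when the residue is invariant across six
basal species (*D. pseudoobscura*, *D. persimilis*, *D. willistoni*,
*D. virilis*, *D. mojavensis*, *D. grimshawi*); a gap or unknown residue
makes the site non-conservative rather than missing, a deterministic and
conservative convention (it can only reduce conservative-site calls).

## Counting rules

For indels at the terminal depth (`a`–`b'`), only substitutions specific
to the *D. melanogaster* branch can postdate the indel, so mel-vs-sec
mismatches are counted only at sites where *D. sechellia* matches
*D. erecta*, with weight 1.  For the deeper configurations (`c`–`f'`)
both the mel and sec lineages inherited (or escaped) the indel, so
mismatches are counted at all sites, and amino-acid substitution counts
are divided by two — each lineage contributes half the path.  The
divergence fractions Dn and Ds are mismatch proportions at
non-degenerate and fourfold sites respectively, deliberately without any
multiple-hit correction: at mel–sec divergences the correction is small,
and uncorrected fractions keep polymorphism and divergence on the same
scale.

A site is polymorphic only when biallelic with **both** alleles in at
least two lines — the standard guard against weakly deleterious
low-frequency amino-acid variants inflating Pn and biasing the
McDonald–Kreitman estimate downward.  Sites with more than half the
panel uncalled are excluded; the rule is applied to SNPs and indel
variants alike for symmetry.  Polymorphism fractions use all eligible
class sites as denominator (not the sec==ere subset used for divergence
in `a`–`b'`): within-species variation segregates today regardless of
the outgroup match, and the contract of the polymorphism counter imposes
no outgroup condition.

The adaptive fraction is `alpha = 1 - (Pn/Ps)/(Dn/Ds)`, computed from
counts pooled across the indel regions of a slice (a configuration, a
distance range); any zero among Ps, Dn, Ds yields an `NA` sentinel.  The
walk length is the sum over the 20 bins (10 codons per bin, 10 bins per
side) of the per-bin difference in mean amino-acid substitutions per
indel, case minus control; per-indel means (rather than pooled counts)
are used because the estimand is a per-indel quantity — the expected
number of extra substitutions one indel triggers.

## Resampling

All confidence intervals are percentile bootstrap intervals over **whole
indel regions** — never individual sites, whose counts are strongly
dependent within a region — with 1000 trials by default and an explicit
seed (identical seeds give identical intervals).  The walk-length CI
resamples case and control regions independently; because the sum of
per-bin mean differences equals the difference of per-indel totals, the
bootstrap operates on per-region totals (`two_sample_mean_diff_ci()`),
whose nominal 95% coverage is verified by simulation in the test suite.
Spearman's rank correlation (average ranks for ties) uses exhaustive
permutation enumeration up to length 8 and the t-approximation beyond.
Fisher's exact test reports the sample odds ratio `ad/bc` (with an
infinite sentinel when `bc = 0`) and the minimum-likelihood two-sided
p-value — the sum of hypergeometric probabilities not exceeding that of
the observed table; fractional substitution weights arising from the
halving rule are summed per cell and then rounded to the nearest integer
before tabulation.

## Indel polymorphism and the neutral yardstick

Polarized polymorphic indels are summarized as an unfolded derived-allele
spectrum.  Under the neutral infinite-sites model the expected density of
derived-allele frequency x is proportional to 1/x, so in a sample of n
sequences the expected count at derived count i is proportional to 1/i
and the mean derived frequency is `((n-1)/n)/H(n-1)`; at n = 162 this is
0.1755.  Observed mean frequencies below this value, and negative
Tajima's D, indicate selection against segregating indels.  Tajima's D is
computed from the spectrum with the standard variance normalization,
treating n as the modal number of called lines (the formula assumes a
constant sample size); for n ≤ 3 the statistic degenerates to 0/0 and is
reported as 0, since pi and Watterson's estimator coincide identically
there.  Frequency-binned output uses intervals of width 0.05 with records
weighted equally and per-record denominators `derived/n_called`.

## What the generator emulates — and what it does not

`simulate_dataset()` creates data with exactly the structure the
estimators assume:

* Codon sequences evolve site-independently along the fixed topology.
  Branch lengths are in expected synonymous substitutions per fourfold
  site (defaults put mel–sec at 0.10); each proposed change is accepted
  when synonymous, with probability `omega` (default 0.15) when
  amino-acid-changing, and never when creating a stop.  This acceptance
  thinning creates the Dn/Ds structure the MK machinery consumes without
  full codon-model machinery.
* Each gene carries at most one indel, placed on the branch its drawn
  configuration implies, with a short length distribution (mostly 1–2
  codons) and a central position so that full 100-codon windows fit; the
  generator refuses gene lengths below 230 codons for that reason.
* Case configurations `a`–`d` receive a burst of `lambda_total` expected
  extra amino-acid substitutions per affected lineage (both mel and sec
  for the shared-branch `c`/`d`, whose counts the estimator halves), at
  geometric distances from the indel edge (scale 25 codons), on the
  N-terminal side with probability `upstream_bias` (default 0.7), and
  preferentially at conservative sites (weight 2).  Each burst event is
  placed at a codon where the counted comparison currently shows no
  difference, so `lambda_total` is the expected number of *observable*
  extra substitutions — the quantity the estimator measures — rather than
  a raw event count partially hidden by saturation.
* Basal-species rows are invariant at a fixed fraction of codon sites
  (default 0.5) and independently drawn elsewhere; within-species SNPs
  appear at fourfold sites with probability `theta` (default 0.01) and at
  non-degenerate sites with probability `theta * omega`, with derived
  counts following the neutral 1/i spectrum in a panel of n = 162;
  polymorphic indels get a singleton excess (stronger for deletions,
  emulating stronger selection against them).

The generator deliberately omits: realistic indel mutational spectra,
rate heterogeneity along genes, alignment error, linkage between
polymorphic sites, recombination, and demography.  Passing the recovery
tests therefore shows that the estimators are correct under their own
assumptions — unbiased recovery of injected walk lengths, adaptive
fractions and frequency spectra — not that real alignments satisfy those
assumptions.

## Numerical choices and degenerate inputs

Coordinates are 0-based half-open internally and 1-based inclusive in
every emitted report.  Empty bins are flagged rather than zero-filled in
pooled fractions; estimators return `NA` sentinels (never errors) for
empty case/control sets, zero denominators in alpha, spectra without
segregating variants, or degenerate rank vectors.  Codons containing `N`
or gaps fall into the excluded degeneracy class; heterozygous VCF calls
are resolved haploid (first allele), as the panel consists of inbred
lines.

## Problem sizes in the checks

The recovery checks run the full pipeline on 500 simulated genes per
injected walk length (0, 1 and 5 substitutions) under a fixed seed,
verifying that the bootstrap CI covers the injected value, that
control-configuration excess is statistically zero, and that pooled alpha
within 40 codons matches the injected adaptive fraction; bootstrap
coverage is measured over 500 known-truth replicates of 200 regions per
arm; goodness-of-fit of the sampled neutral spectrum uses 100,000
variants.  These sizes give Monte-Carlo errors comfortably below the
effect sizes being checked while keeping a full run on one CPU in the
minutes range.

## Limitations

The polarization step is specific to the fixed six-species topology; the
configuration table, not a general parsimony engine, defines it.  The MK
estimate shares the known sensitivities of its family — segregating
weakly deleterious variants (mitigated by the two-line rule), biased gene
conversion, and selection on synonymous sites are not modelled.  The
walk-length estimator measures amino-acid *differences*, so two
substitutions at one codon count once; saturation is negligible at the
divergences the design targets but would bias longer branches downward.
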