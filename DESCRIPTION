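Package: indelwalk
Title: Indel-Triggered Adaptive Walks in Protein-Coding Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and polarizes frame-preserving insertions and deletions
    on a fixed six-species Drosophila phylogeny by Dollo parsimony, counts
    distance-binned synonymous and non-synonymous divergence and polymorphism
    along the Drosophila melanogaster lineage, estimates the fraction of
    adaptive amino-acid substitutions with the McDonald-Kreitman test, and
    measures the length of the post-indel adaptive walk as the case-minus-
    control excess of amino-acid substitutions around the indel site.  Also
    provides the derived-allele site-frequency spectrum of polymorphic indels
    against the neutral infinite-sites expectation, Tajima's D, bootstrap
    confidence intervals over indel regions, and a synthetic-data generator
    that emulates codon sequences evolving on the fixed tree with indel
    events, a decaying post-indel burst of non-synonymous substitutions, and
    neutral within-species polymorphism.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    seqinr,
    e1071,
    vcfR
Config/testthat/edition: 3
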