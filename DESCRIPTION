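Package: coihaps
Title: Haplotype Diversity, Hotspot Covariance and G-Quadruplex Motifs in
    Mitochondrial COI Alignments
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for intraspecific analyses of aligned mitochondrial
    protein-coding sequences (typically the COI barcoding fragment):
    haplotype collapsing, per-population diversity summaries (haplotype and
    nucleotide diversity, segregating sites, mean pairwise differences),
    neutrality tests (Tajima's D and Fu's Fs via the Ewens sampling
    distribution), mismatch distributions with constant-size and
    sudden-expansion expectations, one-level AMOVA with permutation-tested
    Phi-ST and pairwise Phi-ST, principal coordinates analysis, hotspot-key
    haplotype classification with stepwise transition-polarity inference,
    pairwise positional covariance networks, and a QGRS-style G-quadruplex
    motif scanner. A synthetic-data module generates expansion-structured
    alignments with planted haplotype groups and coalescent samples for
    calibrating the neutrality tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
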