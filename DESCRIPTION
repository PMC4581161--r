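Package: variantfunnel
Title: Cross-Lineage Variant Funnel for Backcross Candidate-Gene Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maps causal genes from backcross-derived inbred lineages by
    intersecting per-lineage variant sets called against the recurrent
    parent's genome, predicting codon-level coding consequences of SNVs and
    short indels (including splice-donor/acceptor disruption modeled as
    intron retention), and applying a fixed gene-level exclusion funnel
    (silent variants, inbred-allele truncations, conservative exchanges,
    non-conserved alignment regions). Also characterizes candidate proteins
    (translation, average molecular weight, polyglutamine and proline-rich
    windows), summarizes scaffold-level positional bias of candidates, and
    ships a seeded synthetic backcross generator with planted lesions and a
    ground-truth table for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    S4Vectors,
    vcfR,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    seqinr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
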