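Package: junctionscape
Title: Splice-Junction Signals, Protein Disorder and Exonic Splicing Enhancers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing how splice-site nucleotide signals and exonic
    splicing enhancers interact with protein structure and intrinsic disorder.
    Provides exon phase annotation and codon-level exon-to-protein coordinate
    mapping from GTF gene models, classification of exons as
    structure-encoding or disorder-encoding from per-residue annotation
    tracks, amino-acid composition of splice-junction codons with fold
    changes against proteome background and TOP-IDP disorder-set enrichment
    statistics, Spearman correlation profiles of amino-acid usage with
    distance from splice junctions, hexamer splicing-enhancer density scans,
    and a seeded synthetic gene-model generator that plants recoverable
    signal (splice-site bias, enhancer motifs, composition gradients,
    disorder tracks) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
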