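Package: spacerlink
Title: CRISPR Spacer-Resolved Virus-Host Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers prokaryotic virus-host interactions from metagenome
    assemblies by matching host CRISPR array spacers to protospacers on
    viral scaffolds. Provides CRISPR array detection and spacer excision,
    a mismatch-tolerant spacer-to-protospacer search with BLAST-style
    retention criteria (at most one mismatch, query coverage of at least
    90%, E-value at most 1e-4), bipartite virus-host network construction
    with hyper-targeting and cross-phylum candidate curation, virally
    encoded CRISPR array and interviral conflict detection, provirus
    versus co-binned classification by local alignment thresholds, Chi
    site density analysis, greedy identity-based clustering of viral
    scaffolds into populations, sketch-based MAG dereplication, and
    temporal network comparison. Includes a synthetic community generator
    with a ground-truth manifest so that every detector has a recovery
    test.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
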