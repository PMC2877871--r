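Package: statsites
Title: Phylogenetically Filtered Scanning for STAT Transcription Factor
    Binding Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Locates candidate STAT-regulated enhancers in large
    cis-regulatory regions. Scans DNA for degenerate palindromic STAT
    binding sites (TTCnnnGAA and TTCnnnnGAA), classifies each site as
    phylogenetically conserved or not across an aligned ortholog set,
    merges sites into clusters, selects candidate enhancer regions that
    contain conserved sites, and quantifies site enrichment against an
    analytic uniform or zero-order Markov null model (with a
    composition-preserving shuffle alternative). A neutral-evolution
    simulator with protected intervals generates ortholog sets with known
    ground truth for calibrating the conservation filter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
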