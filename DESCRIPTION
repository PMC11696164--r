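Package: tfhet
Title: Transcription-Factor Occupancy, CCAAT Motifs and Small-RNA Tracks at
    Heterochromatic Repeats
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for transcription-factor (TF) binding inside
    constitutive heterochromatin of fission yeast: fold-enrichment track
    arithmetic (tagged-over-untagged ratio of ratios, 10 bp mean binning,
    interval masking), construction of a merged uniform-width TF binding-site
    library from peak summits, CCAAT-box counting on both strands with gap
    collapse, site-set overlap statistics with hypergeometric enrichment and
    Ward clustering of the occupancy matrix, strand-resolved CP10M-normalized
    small-RNA coverage tracks with SGR output, and cryptic-intron detection
    and homology projection between diverged repeat copies. A seeded
    synthetic-data generator emulates the statistical structure of the inputs
    (repeat families, planted motif clusters, planted ChIP enrichment,
    strand-biased multi-mapping small RNAs, planted GT..AG introns) so every
    stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
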