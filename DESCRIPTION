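Package: wgdretain
Title: Whole-Genome Duplication Detection and Duplicate Retention Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detects paleopolyploidy signatures in plant genomes and traces
    which genes were retained after each whole-genome duplication (WGD).
    Provides protein-guided codon alignment with NG86 and YN00 counting
    estimators of synonymous (Ks) and nonsynonymous (Ka) substitution rates,
    dynamic-programming detection of collinear (syntenic) blocks with tandem
    filtering, trough-split Gaussian fitting of the Ks distribution to locate
    WGD peaks, gene-tree duplication-event classification with sigma/rho
    retention assignment via syntenic blocks, transcription-factor family
    z-score screening, hypergeometric GO over-representation with
    Benjamini-Hochberg correction, and a synthetic genome-evolution simulator
    with ground-truth labels for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
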