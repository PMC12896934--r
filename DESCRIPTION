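Package: hvigor
Title: Heterosis Expression-Pattern Analysis for Two-Parent/Hybrid Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Classifies genes of a two-parent/hybrid expression experiment into
    heterosis expression patterns from mid-parent and best-parent heterosis
    statistics (MPV, MPH, BPH) and per-contrast differential expression,
    prioritizes hybrid-vigor candidate genes, and runs the downstream
    statistics used in heterosis transcriptome studies: Tukey HSD trait
    comparisons with compact letter displays, gene-trait Pearson
    correlations, degree-based hub-gene selection on a user-supplied
    interaction network, and hypergeometric gene-set over-representation.
    Includes a negative-binomial synthetic-data generator with known
    per-gene inheritance modes so the full pipeline is testable without
    access to deposited sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    limma,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
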