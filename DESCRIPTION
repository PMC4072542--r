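Package: bgsmap
Title: High-Resolution Background-Selection Landscapes and Diversity Baselines
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes background-selection (BGS) B landscapes at 1-kb
    resolution from genome annotation, windowed crossover maps with gene
    conversion, and truncated distributions of deleterious fitness effects
    (log-normal, gamma, point-mass, and per-class hybrids). Uses B as a
    baseline for silent nucleotide diversity to detect sweep-like diversity
    deficits and balancing-selection-like excesses via studentized
    residuals with false-discovery-rate control, quantifies the genomic
    scale of BGS (D_B quantiles), and tests efficacy-of-selection
    correlates of B from per-gene dN/dS tables. Includes seeded synthetic
    generators for annotation, recombination maps, polymorphism and gene
    tables so every stage is testable without external data.
License: MIT + file LICENSE
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Biostrings
Encoding: UTF-8
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
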