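Package: holoac
Title: Artificial Chromosome Formation and Holocentromere Domain Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how microinjected DNA fragments concatemerize
    into artificial chromosomes (ACs) in C. elegans and how CENP-A (HCP-3)
    holocentromere domains distribute on them. Provides in-silico restriction
    digestion with provenance-tracked fragment catalogues, a seeded
    non-homologous end-joining concatemer simulator with length-biased
    incorporation and a complete truth table, incorporated/non-incorporated
    fragment classification with a logistic length-bias estimator, CENP-A
    domain characterization (widths, AT-content, occupancy, inter-domain gap
    ECDFs, profile clustering, marker-averaged enrichment), IUPAC degenerate
    consensus scanning, closed-form cytometric/qPCR/segregation
    quantifications, and a synthetic-data generator that emulates AT-structured
    donor genomes and ChIP-like signal tracks so the whole pipeline runs at
    desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
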