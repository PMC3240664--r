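Package: interbandscope
Title: Interval Genomics of Interband-Like Open Chromatin Regions
Version: 0.1.0
Authors@R: person("Interbandscope", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Anchored-window analysis of protein binding tracks around
    reference interband insertion sites, weighted-resampling binomial
    enrichment tests, genome-wide fragment length-class statistics, a pairwise
    co-localization similarity rate with non-metric MDS and hierarchical
    clustering, block-contingency chi-square co-localization tests, and
    chromatin-state composition profiles. Includes a synthetic-data generator
    that plants interband-like loci so the whole pipeline is testable without
    external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    MASS,
    jsonlite,
    stats,
    tools,
    utils
Suggests: testthat (>= 3.0.0), igraph, withr, knitr, rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
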