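Package: poolscan
Title: Pooled-Sequencing Bulked Segregant Analysis for Quantitative Traits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bulked segregant analysis (BSA) of pooled-sequencing marker
    depth tables for quantitative trait locus mapping in backcross
    populations, built around the SNP-index statistic used in silkworm
    cocoon shell weight mapping. Provides the genome-wide SNP-index scan
    with Z-test significance and multiple-testing-corrected linked-marker
    calling, confirmation of putative markers by individual Indel
    genotyping, candidate-region definition and EST-based gene screening,
    expression-phenotype association tests, and gene-cluster interval
    statistics, together with a synthetic BC1 population and pooled-depth
    simulator for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    pracma,
    jsonlite
Config/testthat/edition: 3
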