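Package: hlpascreen
Title: Targeted CNV Screening from Multiplex Ligation Probe Panels
Version: 0.3.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for targeted copy-number-variation (CNV)
    screening with high-throughput ligation-dependent probe amplification
    (HLPA/MLPA-style) panels in pediatric congenital heart disease cohorts.
    Models a 1,602-probe panel covering over 200 recurrent CNV loci on all
    24 chromosomes, simulates probe peak intensities under a multiplicative
    signal model with known copy-number truth, normalizes peak heights to
    probe ratios on the diploid 2.0 scale, calls recurrent-locus CNVs,
    backbone segments and whole-chromosome aneuploidies, classifies calls
    into a five-tier pathogenicity scheme by reciprocal-overlap matching
    against a knowledge base, and computes cohort detection rates and
    case-control association statistics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
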