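Package: herdqc
Title: Quality Diagnostics for Livestock Genome Resequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline of quality diagnostics for whole-genome
    resequencing studies in livestock: logistic saturation modelling of
    variant discovery against sequencing depth with closed-form depth
    solvers, a paired-end read matcher and pileup variant caller with
    depth, allelic-balance and strand-balance filters, subsampled
    variant-recovery curves, an unmapped-read census with a toy greedy
    assembler and best-hit contamination summaries, exhaustive pseudo-read
    fold-enrichment testing for cross-species assembly contamination, a
    per-variant imputation-accuracy scan that flags assembly gaps and
    candidate misassembled regions, and a GBLUP-based single-marker
    association scan. A synthetic-data module generates every input with
    known ground truth so the whole pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Rcpp,
    Biostrings,
    IRanges,
    minpack.lm
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    vcfR,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
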