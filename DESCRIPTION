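Package: esrtools
Title: Quantitative Analysis of Yeast Stress-Response Resource Allocation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the trade-off between stress defense and
    growth in budding yeast. Implements a piecewise Lotka-Volterra two-strain
    competition model under periodic severe stress with analytic phase-state
    classification and a simulation oracle; growth-rate estimation from OD600
    curves with paired wild-type scaling and a short-horizon lag metric; an
    ordinal acquired-stress-resistance survival score over a hydrogen-peroxide
    dose panel; single-cell nuclear-translocation trace metrics with
    iRFP-based strain demultiplexing and population-centered clustering; and
    downstream transcriptome analysis (responsive-gene selection, defect
    calling, k-means partitioning, promoter motif scanning, hypergeometric
    enrichment with Benjamini-Hochberg correction). Seeded synthetic-data
    generators emulate every input class with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    stats,
    utils,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
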