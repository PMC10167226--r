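Package: loopchap
Title: Loop-Motif Hydropathy, Chaperone Activity and Amyloid Aggregation
    Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis toolkit for molecular-chaperone loop
    motifs and protein aggregation kinetics. Scores short sequence motifs
    with residue hydropathy scales (Kyte-Doolittle and the biological
    translocon apparent free-energy scale), quantifies anti-amorphous
    chaperone activity from turbidity kinetics as normalized
    aggregation-mass statistics, fits and applies the linear
    hydropathy-activity relationship with mean-response confidence bands,
    and models amyloid fibril formation with the integrated
    nucleation-elongation-secondary-nucleation rate law, including
    empirical sigmoid fits, numerically safe closed-form simulation and
    constrained global fitting that identifies which microscopic rate
    constant a chaperone suppresses. Includes seeded synthetic-data
    generators for every input, size-exclusion-chromatography oligomer
    size estimation, and small spectroscopy conversions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    minpack.lm,
    pracma,
    lhs,
    jsonlite,
    yaml
Suggests:
    deSolve,
    optparse,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
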