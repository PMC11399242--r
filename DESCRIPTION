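Package: sedconn
Title: Multi-Metric Resting-State fMRI Analysis of Pharmacological Sedation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A surface-based resting-state fMRI pipeline for placebo-controlled
    repeated-measures pharmaco-imaging studies. Builds ROI-level functional
    connectivity graphs and their binarized metrics (edge density, global and
    local efficiency, rich-club coefficient, nodal degree, efficiency and
    betweenness), vertex-wise regional homogeneity (ReHo) on k-hop surface
    neighbourhoods, fractional amplitude of low-frequency fluctuations (fALFF),
    and reference-constrained spatial independent component analysis, together
    with paired repeated-measures inference under Benjamini-Hochberg false
    discovery rate control. Includes a deterministic synthetic-study generator
    with planted sedation effects so the full pipeline can be exercised and
    validated without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    Matrix,
    methods,
    signal,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
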