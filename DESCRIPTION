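Package: phasecalc
Title: Phase-Specific Calcium Imaging and Behaviour Analysis for
    Food Seeking and Consummatory Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for identifying seeking-phase and
    consummatory-phase neurons from calcium imaging of lateral
    hypothalamic leptin-receptor (LepR) neurons. Implements isosbestic
    (405 nm) correction and baseline Z-scoring of fibre-photometry
    signals, derivative-based neural-onset detection via polynomial
    fits (maximum of the third derivative), single-cell phase
    phenotyping from micro-endoscope trace matrices (4-sigma
    responsiveness, NF0 min-max normalization, seeking/consummatory
    scores), brain-slice debleaching and responder calling, sIPSC
    percent-change metrics, pose-keypoint extraction of consummatory
    behaviour bouts, a Venn-style population-composition simulation,
    and single-cell RNA-seq quality-control rules. Seeded synthetic-data
    generators with ground truth make every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    pracma,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
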