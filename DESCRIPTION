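Package: panscreen
Title: Simulation and In-Silico Triage of Antibody Phage-Display Panning Campaigns
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the computational side of a VHH (single-domain antibody)
    phage-display discovery campaign: simulation of multi-round panning under a
    Langmuir selection model with known ground truth, amplicon anchor location and
    framework/CDR annotation of sequencing reads, sequence-liability screening,
    clonotype-level round-to-round enrichment analysis, machine-learning binder
    triage with a PCA/k-nearest-neighbour classifier and a small convolutional
    sequence classifier, candidate aggregation, and downstream assay analyses:
    SPR cross-competition epitope binning, hydroxyl-radical footprinting
    protection calling, and tumor growth inhibition scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    class,
    cluster,
    jsonlite,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
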