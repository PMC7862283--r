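Package: larvalstate
Title: Locomotor State, Anesthesia Emergence and Brain-Activity Mapping in
    Larval Zebrafish
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative pipeline for characterizing lethargy-like behavior
    and delayed emergence from anesthesia in larval zebrafish. Provides
    background-subtraction centroid tracking of lane videos, swim-bout and
    dwell-time segmentation with lap-swimming statistics, constrained
    four-parameter logistic dose-response fitting for multi-endpoint
    anesthesia assays, checkpointed emergence-time analysis (Kaplan-Meier,
    log-rank, Kruskal-Wallis with Dunn post hoc), and voxel-wise
    pERK/tERK brain-activity comparison via Mann-Whitney Z maps with
    FDR-based thresholding and signed median-difference rendering. A
    seeded synthetic-data module generates every input the pipeline
    consumes, so all stages are testable without raw recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tiff,
    minpack.lm,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    survival,
    car,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
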