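Package: necromap
Title: Pixel-Level Accuracy of CT Delineation of Ablation Coagulation Necrosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies how accurately contrast-enhanced CT and CT-perfusion
    parameter maps delineate the histologically defined coagulation-necrosis
    zone after hepatic microwave ablation. Provides threshold windowing with
    seeded region growing, marker/landmark rigid co-registration of histology
    masks to the CT frame, pixel-confusion accuracy metrics (true positive
    rate, false discovery rate, agreement-disagreement ratio), ROC-style
    threshold sweeps with per-ablation and pooled cutoff selection, summary
    ROC curves, size morphometry, a dual-input box impulse-residue-function
    liver perfusion model (forward simulation and parameter estimation), a
    synthetic phantom generator with known ground truth, and minimal DICOM
    input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    pracma,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'dicom.R'
    'imaging-io.R'
    'synthetic-data.R'
    'perfusion.R'
    'isolation.R'
    'coregistration.R'
    'accuracy.R'
    'morphometry.R'
    'study-table.R'
    'pipeline.R'
    'cli.R'
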