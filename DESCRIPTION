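Package: regqa
Title: Quantitative Quality Assurance for Medical Image Registration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for commissioning and routine quality assurance of rigid
    and deformable medical image registration following the AAPM TG-132
    framework. Constructs ground-truth rigid transforms from patient-direction
    shift and rotation specifications, extracts 4x4 matrices from DICOM-style
    spatial registration objects, quantifies per-axis translation errors
    against the half-voxel criterion, measures rotation-axis misalignment via
    the real eigenvector of the rotation block, computes landmark target
    registration error (TRE) statistics from exported deformation vector
    fields, and scores contour propagation with the Dice similarity
    coefficient. Includes a seeded synthetic-fixture generator with exact
    ground truth so every check is testable without external datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
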