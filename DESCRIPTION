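Package: canalregen
Title: Quantification of Mandibular Canal Regeneration from CBCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computer-assisted quantification of bony regeneration of the
    mandibular canal after inferior alveolar nerve transposition, from
    Hounsfield-unit calibrated cone-beam CT volumes. Resamples cross-sections
    perpendicular to a canal centerline, applies dual-threshold (>800 HU
    mature, >400 HU early mineralizing bone) wall detection with four strict
    canal-identification criteria (continuity across sequential sections,
    wall density, >=270 degree circumferential enclosure, tubular
    morphology), and reports the regenerated fraction of the implant-defined
    defect segment. Includes a synthetic CT phantom generator with analytic
    ground truth for validation, NIfTI and NRRD volume I/O, and cohort-level
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
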