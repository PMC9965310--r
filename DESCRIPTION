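Package: rwniche
Title: Semi-Automated Round Window Niche Segmentation and Implant Model Generation
Version: 0.1.0
Authors@R:
    person("RWN", "Tools", email = "rwniche@example.org", role = c("aut", "cre"))
Description: Tools to segment the round window niche (RWN) of the temporal
    bone from cone-beam CT volumes and to derive a printable, patient
    specific implant model. The workflow crops a cubic region of interest
    around the round window, models the round window membrane as an oval
    cut-out of a bilinear saddle surface over four control points, estimates
    a bone threshold from a three-peak intensity histogram, fills the
    half-open niche up to a spill ("water") level measured from a fill
    center, adds a pointed forceps handle, and exports a watertight binary
    STL surface. Includes overlap metrics (volume, membrane contact area,
    Dice, Jaccard, per-rule attribution), minimal NRRD/NIfTI/DICOM volume
    I/O, and a synthetic bone phantom generator with known ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
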