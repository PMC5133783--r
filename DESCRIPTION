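Package: fociquant3d
Title: Quantification of DNA-Damage Foci in 3D Microscopy with Companion
    Survival, Cell-Cycle and CRISPR Verification Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Object-based quantification of DNA double-strand-break foci in
    multi-channel confocal z-stacks: nucleus segmentation, size-filtered 3D
    connected-component foci isolation in two channels (e.g. gamma-H2AX and
    SMC6), per-nucleus overlap counting and condition summaries, with optional
    Richardson-Lucy deconvolution on anisotropic voxel grids.  Companion
    modules analyse clonogenic survival assays (plating efficiency, relative
    survival, paired dose-wise testing), DNA-content cell-cycle distributions
    (peak-anchored phase gating, colcemid depletion kinetics with a
    decay-to-plateau model, division-interval fold changes) and CRISPR edit
    verification arithmetic (protospacer localisation, cleavage-fragment
    prediction, Surveyor indel estimation, in-silico PCR).  A seeded
    synthetic-data generator produces image stacks, colony tables, DNA
    histograms and division tracks with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    EBImage,
    jsonlite,
    minpack.lm,
    Rcpp,
    stats,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
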