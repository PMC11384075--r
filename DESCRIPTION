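Package: novaST
Title: Spatial Transcriptomics Reconstruction for Barcoded Patterned Flow Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts randomly barcoded, nano-patterned sequencing flow cells
    into spatial transcriptomics maps. Provides per-tile spatial barcode
    indexing from demultiplexed FASTQ, fiducial-circle detection on barcode
    density images, tile stitching into a global nanometre coordinate frame,
    tissue-tile identification, error-tolerant barcode matching and UMI
    deduplication, GEM assembly, square binning with quality-control filters,
    and landmark-based affine registration to stained images. Includes a
    synthetic flow-cell simulator that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    Matrix,
    Biostrings,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
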