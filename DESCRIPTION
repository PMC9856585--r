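Package: sliceResponse
Title: Treatment-Response Quantification for Ex Vivo Tumor-Slice
    Fluorescence Assays
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies treatment response in ex vivo cultured tumor-slice
    fluorescence microscopy. Segments nuclei from DAPI/p63 images, applies
    border and minimum-area filters, detects and sizes DNA-damage foci
    (53BP1, RAD51), scores EdU/TUNEL/geminin/p63 positivity, computes the
    RECAP homologous-recombination score from RAD51 foci in geminin-positive
    cells, classifies radiosensitivity from relative proliferation, and
    performs the per-field and per-nucleus statistical comparisons. Ships a
    seeded synthetic slice-image generator with ground truth for validation
    and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tiff,
    EBImage,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
biocViews: CellBiology, FeatureExtraction, Segmentation, Software
RoxygenNote: 7.3.3
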