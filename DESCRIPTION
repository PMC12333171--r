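Package: mscpotency
Title: Secretome Classification, Clinical Scoring and Potency Readouts for
    Conditioned Mesenchymal Stromal Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipelines for studies of PBMC-conditioned mesenchymal
    stromal cells (MSC): quality filtering and differential-secretion testing
    of Olink proximity-extension-assay (NPX) panels; a rule-based six-way
    classification of secretome proteins from per-condition means, packaged
    with a transcribed reference table; the composite global clinical score
    (GCS) used in the humanized NSG-MG mouse model, with baseline
    normalization, humanization filtering and group comparison;
    combinatorial k-of-m surface-barcode design and debarcoding for mass
    cytometry; CFSE dye-dilution proliferation and inhibition readouts; and
    seeded synthetic-data generators with ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    emmeans
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
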