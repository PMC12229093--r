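Package: histex
Title: Contrastive Alignment of Histology and Spatial Gene Expression
    with Histology-Based Expression Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A two-stage framework for spatially resolved transcriptomics
    that (i) aligns spot-level H&E image patches with gene expression
    profiles in a shared 512-dimensional embedding space using
    momentum-distilled contrastive learning plus a binary image-gene
    matching head with hard-negative mining, and (ii) predicts a
    high-expression gene panel directly from histology through a frozen
    image encoder and a transformer decoder trained with mean squared
    error. Includes spot-level preprocessing (center cropping, CPM log
    normalization, highly variable and high-expression gene panels),
    cross-modal retrieval and correlation metrics, a zero-shot whole
    slide image workflow that scores and selects tiles by tissue and
    nuclei content, and a seeded synthetic data generator with a planted
    shared latent signal for end-to-end testing on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    png,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
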