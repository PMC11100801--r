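Package: microquant
Title: Quantification Pipelines for Microglia Imaging and Molecular Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Reusable, tested implementations of the image- and
    assay-quantification procedures used in developmental microglia
    studies: automated cell counting from marker-stained z-stacks, masked
    mean-gray-value measurement, two-dimensional Sholl morphometry on
    skeletonized cells, voxel-level nested-mask engulfment volumetrics
    (lysosomal content and engulfed synaptic material), per-cell Hi/Mid/Lo
    marker-intensity classification, single-cell RNA-FISH puncta scoring,
    pre/postsynaptic puncta colocalization, qPCR and ELISA normalizations,
    and an animal-level aggregation and statistics layer.  A seeded
    synthetic-microscopy generator with exact voxel-level ground truth
    supports end-to-end recovery testing of every stage.
License: MIT + file LICENSE
Imports:
    EBImage,
    emmeans,
    jsonlite,
    Rcpp,
    rlang,
    stats,
    tiff,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
LinkingTo:
    Rcpp
Config/testthat/edition: 3
Encoding: UTF-8
NeedsCompilation: yes
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
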