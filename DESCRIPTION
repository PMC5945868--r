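Package: gwcparc
Title: Individual Whole-Brain Parcellation from Resting-State fMRI by
    Supervoxels and Structured Graph Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Subject-level whole-brain parcellation of resting-state fMRI
    volumes. Voxels are first aggregated into supervoxels by simple linear
    iterative clustering (SLIC) applied directly to the BOLD time series;
    supervoxels are then merged into a requested number of spatially
    coherent, functionally homogeneous parcels by learning a sparse
    affinity graph whose Laplacian is constrained to have exactly as many
    connected components as parcels (a graph-without-cut formulation).
    Includes synthetic phantoms with planted contiguous parcels,
    normalized-cut and SLIC baseline parcellations, random-parcellation
    null procedures, and evaluation metrics: spatial discontiguity index,
    functional homogeneity, and adjacency-matrix Dice reproducibility.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    igraph,
    Matrix,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    mclust
Config/testthat/edition: 3
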