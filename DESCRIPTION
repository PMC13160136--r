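Package: mrvem
Title: Multi-Resolution Volume Electron Microscopy Alignment and
    Reconstruction Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for processing multi-resolution serial block-face
    electron microscopy (SBEM) volumes: discovery and planning of tiled
    acquisitions, patchwise optic-flow registration with elastic spring-mesh
    regularization, XY tile stitching, Z alignment from a root slice,
    registration of synaptic-resolution sub-stacks into a cellular-resolution
    reference frame, affinity-based supervoxel watershed with hierarchical
    agglomeration and chunked-graph export for collaborative proofreading,
    synapse-to-circuit table extraction with autapse and weak-edge filtering,
    and an acquisition time and data-size gain estimator.  Includes a
    synthetic phantom generator producing tiled, deformed, noisy EM-like
    stacks with full ground truth, so the entire pipeline is testable
    end-to-end without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tiff,
    jsonlite,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
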