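Package: contactome
Title: Neuron-Neuron Contact Quantification, Diffusion Condensation and
    C-PHATE Embedding for Volume EM Segmentations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies pairwise neuron-neuron contact (adjacency) from
    segmented volume electron microscopy label stacks, clusters neurons by
    the similarity of their adjacency profiles with diffusion condensation
    (iterative diffuse-and-merge with modularity-based stratum selection),
    builds the C-PHATE block connectivity matrix across condensation
    iterations and embeds every iteration-cluster in 3-D, exports
    cross-iteration cluster flows for Sankey diagrams, and generates
    triangle meshes (isosurfaces, contact patches, synapse glyphs) with
    Wavefront OBJ input/output. Includes synthetic fixture generators (tube
    phantoms with known contact geometry, planted-block adjacency matrices)
    so every stage is testable against exact ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    igraph,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
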