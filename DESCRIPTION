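Package: ionclust
Title: Spatially Aware Clustering of Mass Spectrometry Imaging Ion Images
Version: 0.1.0
Authors@R:
    person("Aspect", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for grouping ion images from mass spectrometry imaging
    (MSI) experiments by spatial expression pattern. Ion images are read
    from imzML, preprocessed (TIC normalization, median baseline
    correction, upper winsorization and unit scaling), and optionally
    converted into fixed-length "neural ion image" embedding vectors by
    splitting each image into overlapping patches of a target physical
    size, embedding each patch, and max-pooling the patch embeddings.
    Regular or neural ion images are clustered with UMAP followed by
    DBSCAN, or with k-means. Clusterings are evaluated with the Relative
    Isotope Ratio: the fraction of isotope-pair images (+1.003 Da,
    spatially correlated) that share a cluster, divided by the expected
    fraction under a size-preserving random relabeling estimated by
    bootstrap. A seeded synthetic MSI generator with ground-truth pattern
    labels and isotope pairs, an expert-score ranking benchmark, and a
    command-line interface are included.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    xml2,
    jsonlite,
    rhdf5,
    uwot,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
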