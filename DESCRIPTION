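Package: scassign
Title: Single-Cell Clustering, Label Transfer, and Cell-Type Annotation Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless, scriptable toolkit for cell-type assignment in
    single-cell data across modalities. Implements quality-control filtering,
    CPM/log1p normalization and unit-variance scaling; PCA/UMAP dimensionality
    reduction; exact k-nearest-neighbour graph construction; Leiden community
    detection including a semi-supervised variant with frozen clusters;
    scATAC-seq gene-activity scoring from peak-by-cell matrices and GTF gene
    models; reference-to-query label transfer by PCA projection and
    neighbour voting with confidence-based cluster freezing and constrained
    refinement; cluster-versus-rest differential expression (Welch's t-test)
    with fold-change-ranked marker selection and hypergeometric gene-set
    overrepresentation; and projection of cluster assignments onto spatial
    (e.g. CODEX) cell centroids with colour-matched side-by-side figures.
    Includes synthetic-data generators so every stage can be exercised and
    validated without external downloads, plus a command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    grDevices,
    withr,
    FNN,
    uwot,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ggplot2,
    patchwork,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    mclust,
    igraph,
    png,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
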