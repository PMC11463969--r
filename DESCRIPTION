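Package: thalamap
Title: Developmental Emergence of First-Order and Higher-Order Thalamic
    Neuron Identity from Single-Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to track how first-order (FO) and higher-order (HO)
    thalamic neuron identities emerge along a differentiation continuum in
    single-cell RNA-seq data. The core is an iterative seed-cell marker
    bootstrapping mapper: mature (postnatal) marker genes score terminal-stage
    cells, the top-quantile cells seed a differential-expression step that
    derives stage-appropriate embryonic markers, and every post-mitotic cell
    is then assigned an identity from the derived marker pseudogenes. The
    package also provides quality control, normalization, highly variable
    gene selection, PCA, shared-nearest-neighbor clustering, rank-sum
    differential expression, graph-geodesic pseudotime, clustering of
    developmentally regulated genes into transcriptional waves, an
    input-deprivation (enucleation) comparison with maturation-lag and
    activity-dependent gene statistics, and a negative-binomial synthetic
    count simulator with full ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    cluster,
    stats,
    utils,
    graphics,
    grDevices,
    methods,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
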