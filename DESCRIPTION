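Package: nodescope
Title: Single-Cell Transcriptomic Dissection of Tumor Heterogeneity and
    Drug Response
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A pipeline for analysing Drop-seq digital gene expression
    matrices from heterogeneous tumors profiled across treatment arms.
    Provides quality-control filtering (species purity, UMI/gene floors,
    outlier and mitochondrial-stress removal), binned-dispersion variable
    gene selection, SVD principal component analysis with z-score
    component selection, shared-nearest-neighbor Louvain-Jaccard
    clustering with hierarchical merging of cluster centroids into nodes,
    bimodal likelihood-ratio differential expression with heuristic
    doublet-cluster detection, projection of query cells into a reference
    PC space via gene loadings with k-nearest-neighbor placement and
    label transfer, independent component analysis of differentiation
    trajectories with cell-cycle phase scoring, per-animal population
    statistics (ANOVA, Fisher's exact, hypergeometric overlap, fold
    changes), and diffusion-based expression imputation with gene-gene
    correlation and treatment-interaction testing.  A synthetic Drop-seq
    cohort generator with full per-barcode ground truth supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    igraph,
    Rtsne,
    ica,
    ape,
    emmeans,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SingleCell, Transcriptomics, QualityControl, Clustering,
    DimensionReduction, DifferentialExpression
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'de.R'
    'reduce.R'
    'ica.R'
    'impute.R'
    'io.R'
    'popstats.R'
    'projection.R'
    'qc.R'
    'simulate.R'
    'pipeline.R'
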