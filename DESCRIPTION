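Package: pansv
Title: Pan-Genome Gene Families, Structural-Variant Catalogs, Selection
    Scans and Marker-Panel Genomic Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analyses for multi-assembly pan-genome studies:
    classification of gene families into core, dispensable and private
    sets with pan/core accumulation curves; merging of structural-variant
    (SV) callsets from different sources into a nonredundant catalog with
    presence/absence (PAV), size-spectrum, genic-region and
    transposable-element annotation; a di-statistic population
    stratification scan over SV genotypes built on pairwise FST;
    integration of stratified SVs with differential-expression and
    chromatin-peak evidence; and single-marker GWAS, SV-SNP linkage
    disequilibrium profiling and cross-validated genomic selection with
    SNP, SV and combined marker panels. A synthetic-data generator with
    recorded ground truth emulates every input so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    S4Vectors,
    vcfR,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
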