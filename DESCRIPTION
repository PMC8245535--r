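Package: lakecycle
Title: Genome-Resolved Biogeochemical Profiling of Stratified Lake
    Microbiomes
Version: 0.99.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for depth-discrete, genome-resolved metagenomics of
    permanently stratified lakes: quality selection and average nucleotide
    identity (ANI) based dereplication of metagenome-assembled genomes
    (MAGs) using MinHash sketches, read-count-normalized relative
    abundance (RAR) across a depth gradient, rule-based assignment of
    carbon, nitrogen and sulfur cycling reactions to genomes from HMM hit
    tables, abundance-weighted reaction profiles per depth zone,
    cross-lake ANI and endemism comparison, concatenated
    ribosomal-protein supermatrix construction, and a synthetic
    stratified-community generator with full ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Depends:
    R (>= 4.3)
Imports:
    Biostrings,
    jsonlite,
    methods,
    Rcpp,
    S4Vectors,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Encoding: UTF-8
biocViews: Metagenomics, Microbiome, Sequencing, Software
RoxygenNote: 7.3.3
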