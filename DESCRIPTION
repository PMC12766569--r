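Package: edittrace
Title: Lineage Tracing with Irreversible Edit Marks: Simulation,
    Reconstruction, and Spatial Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Toolkit for evolving lineage-tracing experiments that record
    cell ancestry through irreversible installation of lineage marks (LMs)
    at genomic edit sites. Simulates birth-death phylogenies with
    stochastic mark accrual and detection dropout; reconstructs trees from
    categorical character matrices by weighted-Hamming neighbor joining,
    UPGMA, and a greedy splitter; scores reconstructions with normalized
    Robinson-Foulds distance, depth-normalized triplets correct, and the
    Fowlkes-Mallows index against static barcode groups; infers ancestral
    states by Sankoff parsimony with asymmetric transition costs and
    estimates branch lengths in days under a constant-rate editing model;
    performs sequencing-readout quality control and clone calling from
    UMI tables; decodes imaging spot intensities to integration barcodes
    with an expectation-maximization intensity model; and computes joint
    spatial-lineage statistics such as Moran's I autocorrelation and
    local lineage-mark diversity.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    data.table,
    Matrix,
    mclust,
    minpack.lm,
    nnet,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
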