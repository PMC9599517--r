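Package: phagepan
Title: Circularization, Pan-Genome and Gene-Module Analysis of Environmental Phage Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recovering complete environmental phage genomes from
    assembled metagenome contigs by terminal direct-repeat circularization,
    calling ORFs on circular genomes, clustering proteins into orthogroups,
    computing pan/core-genome statistics and average amino-acid identity (AAI),
    delineating phylogenetic clades that are coherent and supported in two
    independent trees, and detecting colocated auxiliary metabolic gene (AMG)
    partners and Type VIII secretion system (Curli) gene modules, with
    composition typing, family assignment and per-station frequency profiling
    of virome data. Includes a synthetic-data generator that plants known
    clades, orthogroups, terminal repeats and gene modules so that every stage
    of the pipeline is verifiable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    ape,
    igraph,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    rtracklayer
Config/testthat/edition: 3
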