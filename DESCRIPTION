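Package: PromiScreen
Title: Genome-Wide Prediction of Promiscuous Enzyme Functions and
    Multicopy Suppression
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts promiscuous ("underground") enzyme functions of
    metabolic genes by an iterative profile search that recruits distant
    homologs (align, cluster, trim, position-specific search, filter),
    assembles a gene-by-promiscuous-function matrix, and derives
    target-replacer gene pairs in two modes: direct pairs, where a
    replacer's promiscuous function equals a target's primary function,
    and indirect pairs, where adding the promiscuous reaction to a
    genome-scale metabolic model rescues flux-balance growth after target
    knockout on minimal medium. Ships deterministic synthetic-fixture
    generators (planted distant homologs at controlled percent identity;
    a toy metabolic model with a conditionally essential pathway and a
    planted bypass reaction) so the whole pipeline is testable offline,
    plus hypergeometric overlap and reciprocity statistics for comparing
    predictions with multicopy-suppression screens.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    Matrix,
    ape,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Software, SystemsBiology, Metabolomics, SequenceMatching,
    Alignment, NetworkInference
RoxygenNote: 7.3.3
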