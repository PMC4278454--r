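Package: ZWstrata
Title: Gametolog Divergence, Evolutionary Strata and Gene Conversion on
    Avian ZW Sex Chromosomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for inferring the evolutionary history of avian ZW sex
    chromosomes from coding sequence. Identifies W-linked genes from sexed
    expression profiles and sequence similarity, pairs Z and W gametologs by
    reciprocal best hit with a next-best fallback, estimates pairwise
    synonymous and nonsynonymous divergence by maximum likelihood under a
    codon substitution model (with a Nei-Gojobori counting oracle), assigns
    gametologs to evolutionary strata and dates recombination suppression
    with a sex-specific molecular clock, classifies shared versus independent
    suppression from bootstrapped maximum-likelihood gene trees, detects
    Z-W gene conversion with a silent-site fragment permutation test, and
    tests selective regimes with branch and branch-site likelihood-ratio
    tests. A forward simulator of gametolog histories generates fully
    labelled synthetic datasets so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
biocViews: Genetics, Phylogenetics, SequenceMatching, Alignment
RoxygenNote: 7.3.3
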