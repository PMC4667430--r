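Package: CladeScope
Title: Pan-Genome, Nucleotide-Identity and Phylogroup Analysis for Bacterial Clades
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Comparative-genomics toolkit for bacterial clades at the
    genus-to-family scale. Builds pan- and core-genome gene families by greedy
    accumulation and by reciprocal-best-hit orthology with two-stage (Markov
    cluster plus single-linkage) clustering, together with rarefaction curves
    and contig-fragmentation sensitivity analysis. Computes fragment-based
    average nucleotide identity (ANI) and total nucleotide identity (TNI)
    matrices and their per-taxonomic-rank distributions. Provides tree-based
    phylogroup delimitation by minimising the intersection area between
    within-group and between-group distance distributions under a monophyly
    constraint, and node-depth analysis of metabolic traits. Includes screens
    for cell-envelope proteases (catalytic triad, domain architecture and
    cell-wall anchor class), plasmid-derived contigs, CAZyme hit
    reconciliation, glycolysis gene presence and niche association, plus a
    genome-evolution simulator (birth-death trees, gene gain/loss, Jukes-Cantor
    divergence, draft fragmentation and planted features) that supplies ground
    truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    ape,
    igraph,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
biocViews: ComparativeGenomics, Phylogenetics, Software
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
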