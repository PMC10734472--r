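Package: flexgi
Title: Discovery and Ecological Typing of Flexible Genomic Islands from
    Metagenomic Read Recruitment
Version: 0.1.0
Authors@R:
    person("flexgi", "developers", email = "flexgi@example.org",
           role = c("aut", "cre"))
Description: Tools to detect and type flexible genomic islands (fGIs) in
    streamlined marine bacteria from metagenomic read recruitment.
    Implements RPKG-normalized recruitment at dual nucleotide-identity
    tiers, coverage-depletion island delimitation, fragment-based average
    nucleotide identity (ANI) with greedy dereplication and genomospecies
    assignment, gene-content typing of phosphate (fGIp A-H) and
    phosphonate (fGIphn A-D) island versions, island-versus-genome
    average amino-acid identity (AAI), and exact nonparametric statistics
    (Wilcoxon signed-rank, Spearman, Kruskal-Wallis) linking island
    variants to environmental phosphate.  A synthetic-community module
    generates clonal populations, island versions along a phosphate
    gradient, and shotgun metagenomes with full ground truth so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
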