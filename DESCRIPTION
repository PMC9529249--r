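Package: ghostDex
Title: Ghost-Lineage Introgression Statistics for Pseudo-Haploid Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detection and attribution of ancestry from unsampled ("ghost")
    lineages in pseudo-haploid genome data. Implements the four-taxon
    ABBA-BABA D statistic with block jackknife/bootstrap standard errors, an
    extended D (D_ex) statistic that ascertains lineage-specific derived
    alleles against multiple conditioning outgroups, disentangling of
    low-frequency derived-allele sharing across outgroup individuals,
    identity-by-state distances with neighbour-joining trees, genomic-region
    pseudo-bootstrap node supports and classical MDS, N-masked mitochondrial
    pairwise-difference summaries, and a fully seeded synthetic-data generator
    (population-tree drift, ghost admixture, pseudo-haploid sampling) that
    provides ground truth for every analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    Biostrings,
    ape,
    data.table,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn
biocViews: PopulationGenetics, SNP, Phylogenetics, Sequencing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
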