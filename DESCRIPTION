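Package: markerscan
Title: Evaluation of Protein-Coding Marker Genes for Bacterial Community
    Profiling by In Silico PCR, Nucleotide Diversity and Variable-Site
    Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to evaluate candidate marker genes (such as the
    housekeeping gene gyrA) against the 16S rRNA gene for taxonomic
    profiling of bacterial genera such as Bacillus. Implements degenerate
    primer expansion and in-silico PCR with a minimum-identical-base
    amplifiability rule, sliding-window nucleotide diversity (pi),
    reference-anchored variable-site (SNP) profiling of marker
    sub-regions, and mock-community resolution analysis of amplicon
    sequence variants. A synthetic-data generator produces genomes,
    marker alignments, mock communities and amplicon reads with known
    truth so every stage can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    BiocGenerics
Config/testthat/edition: 3
biocViews: Sequencing, Microbiome, Genetics
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'seqio.R'
    'diversity.R'
    'snp.R'
    'primers.R'
    'pcr.R'
    'resolution.R'
    'simulate.R'
    'cli.R'
    'markerscan-package.R'
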