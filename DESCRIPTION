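Package: epiline
Title: Natural Epiallele and LINE1 Insertion Analysis for Arabidopsis Accessions
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying naturally occurring DNA methylation epialleles
    created by LINE1 retrotransposon insertions in Arabidopsis thaliana
    accessions. Detects non-reference transposable-element insertions from
    discordant paired-end read alignments with target-site-duplication (TSD)
    calling; quantifies per-context (CG/CHG/CHH) DNA methylation and simulates
    methylation-sensitive restriction PCR (Chop-PCR) scoring; classifies
    accessions into epiallele categories; tests Mendelian segregation and maps
    an epiallele locus by recombinant counting in selected F2 populations;
    dates a retrotransposon insertion with star-phylogeny and
    most-recent-common-ancestor estimators under the Tamura-Nei (TN93)
    substitution model; and tests associations between methylation status and
    bioclimatic variables at two epochs. A synthetic-data generator with known
    ground truth (planted insertions, beta-binomial bisulfite counts, Mendelian
    crosses, TN93 sequence evolution, climate tables) exercises every stage.
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
    GenomicRanges,
    S4Vectors,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    phangorn
Config/testthat/edition: 3
biocViews: Epigenetics, DNAMethylation, Transposon, Phylogenetics, Software
RoxygenNote: 7.3.3
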