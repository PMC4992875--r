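Package: endolith
Title: Multi-Marker Amplicon Metabarcoding and Evolution of the
    Coral-Endolithic Lifestyle
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for multi-marker amplicon metabarcoding of
    coral-skeleton microbiomes: in-silico demultiplexing of pooled 16S, 18S,
    23S rDNA and tufA amplicons by primer recognition, paired-end merging and
    quality control, abundance-ordered greedy centroid OTU clustering with de
    novo chimera screening, naive Bayes k-mer taxonomic classification with
    bootstrap confidence, and three-tier OTU-table filtering against negative
    controls and rare counts.  A companion module fits a two-state Markov
    model of the coral-endolithic trait on a dated green-algal phylogeny,
    draws stochastic character maps, and counts independent origins of the
    endolithic lifestyle.  A synthetic-community generator produces amplicon
    reads and trait-bearing phylogenies with known ground truth so that every
    stage is verifiable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    Rcpp,
    S4Vectors,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
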