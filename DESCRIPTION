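Package: temir
Title: Identification and Validation of Transposable-Element-Derived Plant miRNA Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for recognizing transposable-element-derived
    plant miRNA genes (TE-MIRs) and tracing their regulatory footprint. The package
    screens annotated miRNA stem-loops against a repeat library by local alignment with
    Karlin-Altschul E-values, profiles small-RNA reads on each hairpin (strand bias,
    genome multiplicity, length-class spectrum), applies plant miRNA annotation criteria
    (precise miR/miR* duplex excision, low genome hit, plus-strand bias) to separate
    bona fide miRNAs from hairpin siRNA loci, discovers initial-target protein-coding
    genes created by cognate TE insertion into coding sequence, scores sRNA-target
    complementarity with the plant penalty scheme and minimum-free-energy ratio, and
    validates targeting from degradome 5'-tag profiles summarized by a 1-7 cleavage
    score. A synthetic-data module generates genomes, TE families, hairpin loci,
    small-RNA read sets and degradome tags with known ground truth so every stage is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
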