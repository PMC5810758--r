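Package: crisprArrayKit
Title: Design, Construction and Activity Scoring of Arrayed CRISPR-Cas9
    Knockout Libraries
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building focused, arrayed CRISPR-Cas9 knockout
    sgRNA libraries and for quantifying their editing activity. Implements
    isoform-aware target-exon selection (first CDS exon shared by all
    isoforms, with a primary-variant fallback), tiered sgRNA selection with
    specificity-score and non-overlap rules, peptide-remaining prediction,
    Golden-Gate oligo design, 96-well arrayed layouts and derived pools,
    capture-probe region design, sgRNA representation counting from
    amplicon reads, and in/del-based editing quantification from
    target-enrichment alignments with control subtraction and the Observed
    Activity Score (OAS). A synthetic-data generator emits genome,
    annotation, pool reads and edited/control alignments with recorded
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    rtracklayer,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CRISPR, Sequencing, Alignment, GenomeEditing, Software
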