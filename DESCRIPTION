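Package: prc2strat
Title: Stratification and Quantification of Polycomb (PRC2) ChIP-Seq Targets
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multi-condition ChIP-seq signal quantification around a common
    Polycomb peak set: peak-centered binned signal matrices, RPKM / input
    subtraction / wild-type-relative / spike-in normalizations,
    stratification of targets into signal classes by Pearson-distance
    k-means with elbow-based model selection, bootstrap-of-medians
    cluster-level quantification with percentile confidence intervals,
    DNA-shape (helix twist) conditioned GCG trinucleotide counting, and
    hypergeometric gene-set enrichment against configurable backgrounds.
    Includes a fully synthetic study generator (genome, two-armed peak
    universe, per-condition Poisson coverage, spike-in counts) so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
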