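Package: flkscan
Title: Hierarchical FLK and hapFLK Genome Scans for Selection Signatures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection of selection signatures in structured populations using
    the kinship-rescaled differentiation statistic FLK and its haplotype
    extension hapFLK. Population trees are built from Reynolds distances by
    Neighbor-Joining and rooted on an outgroup; the drift covariance (kinship)
    matrix derived from the tree rescales allele-frequency differentiation into
    an approximately chi-squared test. hapFLK fits a haplotype-cluster mixture
    model to unphased genotypes by EM and applies the multiallelic form of FLK
    to local cluster frequencies, averaged over EM runs, with robust-normal
    calibration. The package includes within-group scans, a between-group scan
    on estimated ancestral allele frequencies, Storey q-value FDR control,
    region calling and candidate-gene ranking, PLINK ped/map input, and a
    forward simulator of drifting structured populations with linkage
    disequilibrium and injected selective sweeps for power and false-discovery
    evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
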