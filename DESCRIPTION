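Package: hashdemux
Title: Hashtag-Oligo Demultiplexing and Doublet Detection for Pooled
    Single-Cell Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for cell hashing experiments, in which samples are
    labelled with DNA-barcoded antibodies (hashtag oligos, HTOs), pooled,
    and demultiplexed after droplet-based single-cell sequencing.
    Quantifies tag UMIs per cell barcode from raw paired reads with
    hamming-distance-tolerant tag assignment, classifies every droplet
    as singlet, cross-sample multiplet or negative using centered
    log-ratio normalization, k-medoids clustering and per-tag negative
    binomial background thresholds, rescues low-UMI barcodes with frozen
    thresholds, and computes flow-cytometry-style staining indices for
    antibody titration series. Includes a droplet simulator with known
    ground truth and closed-form Poisson loading expectations for
    reasoning about super-loading.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    MASS,
    cluster,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
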