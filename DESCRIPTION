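Package: cwselm
Title: Weighted Similarity Extreme Learning Machines for Ligand-Based
    Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ligand-based virtual screening with similarity-activated
    extreme learning machines. Implements sixteen similarity and
    dissimilarity coefficients for binary molecular fingerprints, the
    weighted-similarity extreme learning machine (WS-ELM) with
    class-imbalance weights and a ridge-regularised output layer, and its
    clustering-based variant (CWS-ELM) whose hidden nodes are selected
    deterministically by k-means medoid extraction or by support vector
    clustering (SVDD) with similarity-coefficient kernels. Includes the
    similarity-searching baseline, early-recognition metrics (hit rate,
    enrichment factor, AUROC, BEDROC, enrichment curves), Kendall's
    coefficient of concordance with tie correction, a MUV-style synthetic
    fingerprint generator, fingerprint-table input/output, and the
    split/cross-validation benchmarking protocol.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    graphics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    pROC,
    jsonlite,
    ChemmineOB
Config/testthat/edition: 3
RoxygenNote: 7.3.3
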