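Package: hypoxiscore
Title: Hypoxia Gene-Expression Relapse Risk Scoring from qPCR Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Relative quantification of gene-panel qPCR data by the
    comparative delta-delta-Ct method with housekeeping, stability-selected
    (NormFinder-style) or global-mean normalization; group-wise fold-induction
    profiling between clinicopathological groups; unsupervised hierarchical
    clustering of patients on delta-Ct profiles; Kaplan-Meier relapse-free
    survival with the Mantel-Haenszel (log-rank) test; and construction of an
    indicator-sum relapse risk score from survival-optimized per-gene
    expression thresholds. Includes a synthetic-cohort simulator with planted
    signature effects and ground truth so the whole pipeline can be exercised
    and validated without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    withr,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
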