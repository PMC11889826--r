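Package: ctfrag
Title: Tumor-Agnostic ctDNA Quantification and Fragmentomics from Shallow WGS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies circulating tumor DNA from low-coverage whole-genome
    sequencing of plasma cell-free DNA without tumor-tissue sequencing. Computes
    copy-number instability scores (CPA and the patient-informed ctCPA), five
    cfDNA fragmentomic markers (short-fragment proportion P126-135 and its
    deviation D126-135, end-motif diversity, Alu CGN/NCG end-motif ratio, and
    information-weighted fraction of aberrant fragment ends), calibrates
    per-marker detection thresholds at fixed specificity on a healthy cohort,
    combines markers into residual-disease calls, classifies longitudinal
    biomarker kinetics (clearance, double-negative, residual-positive; risk
    groups A/B), and runs survival analyses for marker-defined strata. Includes
    a synthetic cfDNA cohort generator emulating fragment-length periodicity,
    end-motif composition, recurrent end positions, Alu CpG end motifs,
    copy-number signal, and outcome models so the full pipeline is testable
    without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    Biostrings,
    GenomicRanges,
    IRanges,
    Rsamtools,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
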