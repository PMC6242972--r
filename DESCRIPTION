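Package: crcprior
Title: Prioritization of Super-Enhancer-Marked Dosage-Sensitive Transcription
    Factors on Gained Chromosome Arms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrative pipeline for prioritizing super-enhancer (SE)
    marked, dosage-sensitive candidate oncogenes on a recurrently gained
    chromosome arm (the motivating case is 17q gain in high-risk
    neuroblastoma). Per-sample H3K27ac super-enhancer calls are clustered
    across cell lines, ranked by median within-sample rank, filtered by
    cross-sample recurrence, annotated to nearby genes, and reduced to
    transcription factors with an active (H3K27ac-marked) transcription start
    site in every SE-harboring sample. Candidates are then scored by
    Kaplan-Meier survival stratification at the median expression cut-off,
    and by copy-number dosage effects on expression (focal-amplification
    detection and two-way ANOVA). Bespoke auxiliary computations are
    included: a sliding-window z-score interaction caller for 4C-seq
    fragment coverage with FDR control and domainograms, Excess-over-Bliss
    drug-synergy scoring of dose checkerboards and confluency time courses,
    and rank-based expression signature scoring. A seeded synthetic-data
    module generates every input class (SE landscapes, tumor cohorts with
    linked expression, survival and copy number, 4C fragment tracks, and
    Hill-surface checkerboards) so the full pipeline can be exercised and
    calibrated without external data.
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
    lmtest,
    purrr,
    readr,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    car,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
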