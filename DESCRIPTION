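Package: eposwitch
Title: Developmental Hepatic-to-Renal Erythropoietin Switch Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of the developmental switch of
    erythropoietin (EPO) production from the foetal liver to the kidney.
    Provides a synthetic-data generator for neonatal IEF-PAGE lane
    densitometry and liver-organoid RNA-seq count matrices; band detection,
    acidic/neutral/basic region calibration and foetal/mixed/adult profile
    classification for gel lanes; contingency-table association testing of
    profile class against ordered developmental-age groups with an
    oxygen-decoupling test and logistic maturation-parameter recovery; and an
    organoid expression time-course toolkit (median-of-ratios size factors,
    stabilised marker trajectories, EPO competence-window summaries, hypoxia
    induction testing, 2^-DeltaCt quantification and PCA diagnostics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    limma,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    jsonlite,
    optparse
Config/testthat/edition: 3
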