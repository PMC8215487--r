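Package: evrppa
Title: Reverse-Phase Protein Microarray Analysis of Extracellular Vesicle Cargo
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: End-to-end analysis of reverse-phase protein microarray (RPPA)
    data from serum extracellular vesicles: slide-level normalization
    (local background, negative-control and total-protein correction),
    absolute quantification against synthetic-peptide reference curves,
    limit-of-detection estimation from EV mixture series, cohort
    differential analysis with clinical risk stratification, ROC-based
    cut-off discovery, k-of-n composite signature scoring, and
    unsupervised views (Z-score hierarchical clustering, covariance PCA).
    Includes a seeded synthetic-data generator that emulates the assay
    geometry (triplicate spots, two print concentrations, dilution
    curves, negative-control and total-protein channels) so the whole
    pipeline is testable without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, jsonlite, yaml, ape
Suggests: testthat (>= 3.0.0), pROC, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
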