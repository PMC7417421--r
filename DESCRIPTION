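Package: aadyn
Title: Recurrence and Spatial-Variability Analysis of Atrial Activity
    During Persistent Atrial Fibrillation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Noninvasive characterisation of short- and long-term atrial
    activity (AA) dynamics during persistent atrial fibrillation from
    multichannel body-surface recordings. Computes block-wise multi-variable
    AA recurrence signals and their characteristic indices (LTR, |P1|, P2,
    t_P1, t_P2 and LTR-normalised variants), the SVAAP spatial-variability
    measure based on the knee of the scaled singular-value spectrum at
    one-cycle and 5-s time scales, a stochastic phenomenological generator of
    pseudo-AA signals driven by bounded random-walk phase modulation, the
    standard pre-filters and Welch-based dominant-frequency estimation, a
    grid-search procedure that fits the generator to observed recurrence
    indices, and a thin logistic-regression association utility.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    jsonlite,
    pROC,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'aadyn-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'AASignalSet.R'
    'RcppExports.R'
    'simulator.R'
    'recurrence.R'
    'svaap.R'
    'preprocess.R'
    'fitting.R'
    'association.R'
    'io.R'
    'pipeline.R'
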