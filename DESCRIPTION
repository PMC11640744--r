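Package: soxfe
Title: Self-Organized Explainable Feature Engineering for Multichannel EEG Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the ChMinMaxPat channel-identity feature extractor for
    multichannel EEG segments (per-timepoint extreme-channel identities, six
    transition tables, six map signals and 15 derived feature vectors),
    cumulative-weight neighborhood component analysis (CWNCA) feature
    selection, an iterative/ensemble k-nearest-neighbour classifier (tkNN)
    with iterative majority voting (IMV) fusion, and a Directed Lobish (DLob)
    symbolic explainability layer producing per-feature-vector symbol
    strings, Shannon entropies and directed transition (connectome) matrices.
    Includes a class-structured synthetic EEG generator, grouped
    cross-validation (k-fold and leave-one-record-out), performance metrics
    and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
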