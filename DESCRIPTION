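Package: mddfusion
Title: Multi-Modal MRI Classification of Depression Diagnosis and Outcome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for multi-modal MRI classification of major
    depressive disorder (MDD) diagnosis and 6-month treatment outcome.
    Implements construction of eleven tabular feature sets, including
    wavelet-coherence network-interaction features (static functional
    connectivity, number of coherence clusters, lead coherence) computed
    from resting-state network time series; double feature ranking
    (univariate normality-gated screening followed by minimum-redundancy
    maximum-relevance or concave-minimization SVM ranking) inside nested
    leave-one-out cross-validation with linear support vector machines;
    three multi-modal fusion strategies (concatenation, forced fusion,
    majority-vote ensembles); and the inferential layer: pipeline-preserving
    permutation tests, bootstrap confidence intervals for the AUC,
    FDR-corrected mass-univariate group screens, and contribution/ablation
    feature analyses. A synthetic-cohort module emulates the statistical
    structure of the clinical data so the whole workflow is exercised
    end-to-end without access to MRI recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    EBImage
Config/testthat/edition: 3
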