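Package: gipso
Title: Genetically Inspired Particle Swarm Optimization for Recurrent
    Anomaly Detection in Heart-Rate Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tunes lightweight recurrent neural-network classifiers for
    anomaly detection in univariate heart-rate time series using a hybrid
    particle swarm optimizer augmented with genetic blend crossover,
    parameter mutation and worst-agent replacement (GIPSO). Provides the
    full tuning harness: a mixed continuous/integer hyperparameter search
    space, an Elman recurrent classifier trained by backpropagation
    through time with early stopping, lag-window construction and
    chronological splitting of labeled series, a synthetic arrhythmia
    series generator, classification metrics including Cohen's kappa and
    confusion-matrix reconstruction from printed report rows, a
    multi-run statistical comparison protocol (Shapiro-Wilk screening,
    exact Wilcoxon signed-rank), and sampling-based Shapley attribution
    of lag features.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
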