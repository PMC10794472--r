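Package: passid
Title: Subspace State-Space Modeling and Classification of Photoacoustic
    Sensor Signals
Version: 1.0.0
Authors@R:
    person("Miguel", "Delgado", email = "m.delgado@example.org",
           role = c("aut", "cre"))
Description: Simulates photoacoustic (PA) blood sensor traces as underdamped
    second-order impulse responses, estimates discrete-time state-space models
    from single traces by subspace identification (block-Hankel projection,
    SVD order selection, shift-invariance least squares), converts fitted
    models to continuous time and to a canonical modal form yielding four
    physical features (decay constant, natural frequency, two mode-mixing
    coefficients), computes benchmark time-domain, frequency-domain and
    ARMA(2,2) feature families, and classifies five blood classes (healthy
    female/male, microcytic and macrocytic anemia, leukemia) with linear
    discriminant analysis, one-way ANOVA with Bonferroni post hoc tests,
    confusion matrices and 95% confidence ellipses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
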