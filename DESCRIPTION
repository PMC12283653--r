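Package: crownprof
Title: Crown Profile Prediction with a Layered Directional Competition Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Individual-tree crown profile modelling for even-aged conifer
    stands. Measured directional crown radii are regularized onto a uniform
    relative-crown-height grid by shape-preserving piecewise cubic Hermite
    interpolation; a layered, direction-aware Crown Profile Competition
    Index (CPCI) is computed from Voronoi competitor units and circle-overlap
    geometry; and crown radius at every height layer is predicted by
    sequence neural networks (vanilla LSTM, CNN-LSTM, and CNN-LSTM with
    time-step attention) trained by backpropagation through time, with
    particle swarm hyperparameter search, a five-statistic evaluation suite,
    permutation feature importance, and a synthetic stand generator for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    pracma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
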