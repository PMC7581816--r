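Package: dtmn
Title: Deep Time-Delay Markov Networks for Emotional State Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits hybrid hidden-Markov / time-delay neural network models
    (DTMN) to labeled time series of speech-embedding features, for
    predicting discrete emotional states (angry, high stress, low stress,
    neutral, soft) from the present feature vector and the recent history
    of inferred hidden states.  Includes categorical-emission hidden
    Markov model estimation by Baum-Welch, a from-scratch time-delay
    neural network with sub-sampled temporal contexts trained by
    mini-batch stochastic gradient descent with batch normalization,
    finite Markov chain estimation of state-transition structure,
    a synthetic sequence generator with label-conditional Gaussian
    features, and evaluation utilities (prediction error rate, confusion
    matrices, hidden-state and temporal-context ablations).
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    nnet,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
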