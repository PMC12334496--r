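Package: paddleRL
Title: Reinforcement Learning of Metachronal Paddling at Zero Reynolds Number
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates a two-dimensional zero-Reynolds-number swimmer with an
    elongated body and pairs of rigid paddles, solving the force-free mobility
    problem with the method of regularized Stokeslets, and couples the fluid
    environment to a tabular Q-learning agent that discovers paddle
    coordination strokes.  Provides a deterministic reward-graph cache, an
    exact maximum-mean-cycle oracle for the optimal average-speed gait, and
    stroke analytics (swimming speed, phase lag, paddle amplitude, Lighthill
    efficiency) together with a command-line driver for reproducible training
    runs and paddle-spacing sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    igraph,
    data.table,
    pracma,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
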