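Package: mirnn
Title: Physically Constrained Recurrent Neural Networks and Bayesian
    Experimental Design for Microbial Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Models microbial community dynamics with a physically
    constrained autoregressive recurrent neural network (MiRNN) whose
    constraint forbids the spontaneous emergence of absent species and
    whose rectified outputs forbid negative abundances. Parameters are
    estimated by maximum a posteriori Newton optimisation with a
    Gauss-Newton Laplace approximation of the posterior, giving linearized
    posterior predictive distributions with separate aleatory and
    epistemic components. A fast batch expected-information-gain
    acquisition based on low-rank Woodbury updates, combined with a
    predicted-profit term, drives a greedy batch design selector inside a
    closed-loop design-test-learn optimizer. A fed-batch consumer-resource
    bioreactor simulator supplies ground-truth communities for benchmarking
    and for sparse-community cross-validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
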