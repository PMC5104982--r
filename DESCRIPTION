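Package: bteflow
Title: Transfer Entropy, Backward Transfer Entropy and Directed
    Information Flow for Paired Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact and plug-in estimation of directed information measures
    for paired stochastic time series: transfer entropy, backward transfer
    entropy (transfer entropy of the time-reversed series), directed
    information, the discrete learning rate and the sensory capacity of
    bipartite sensor models.  Includes a surrogate-data test for hidden
    Markov structure, closed-form Gaussian information measures with
    Granger causality and anti-causality (the factor-of-two equivalences),
    numerical verification of generalized second-law bounds and the
    integrated fluctuation theorem on exactly enumerable delayed bipartite
    Markov models, and Kelly-gambling wealth-growth bounds with causal and
    anti-causal (cheating) bookmakers.  All quantities are reported in nats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
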