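Package: orcaseq
Title: Call-Combination Analysis for Killer Whale Vocal Sequences
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for detecting non-random call combinations in tagged
    killer-whale acoustic records. Implements acoustic quality gating based
    on a band-limited signal-to-noise ratio over the 90% energy duration,
    maximum-likelihood estimation of a bout criterion interval from a
    two-process Poisson mixture of inter-call gaps, first-order Markov
    transition analysis with Monte-Carlo chi-squared testing on fixed-margin
    null tables, post-hoc standardized-residual tests with Bonferroni
    correction, extraction of call-combination clusters from the
    significant-transition graph, and association of transitions with
    feeding context via tail-slap proximity. Ships a synthetic call-stream
    generator with planted combination grammars so the full pipeline is
    testable without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
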