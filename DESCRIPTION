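Package: CrossingRuns
Title: Exact Joint Distribution of Crossings and Longest Run in Bernoulli Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes, by an exact iterative recursion, the joint distribution
    of the number of centre-line crossings C and the length of the longest run
    L in a sequence of independent Bernoulli observations, with constant or
    per-position success probabilities.  All arithmetic is exact rational
    (arbitrary-precision integer numerators over a common denominator), so
    results such as the integer-valued symmetric "times" representation and
    the binomial crossings marginal are reproduced exactly.  Includes the
    Anhoej run-chart rules (shift and crossings) with exact specificities and
    sensitivities, a brute-force enumeration oracle, a seeded Monte-Carlo
    simulator, exact CSV/JSON serialization, and a command-line interface.
License: MIT
Encoding: UTF-8
Imports: methods, stats, utils, jsonlite, optparse
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
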