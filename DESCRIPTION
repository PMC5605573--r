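Package: wfage
Title: Exact Allele Age and Absorption Analysis for Wright-Fisher Markov Chains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Exact computation of the moments of the allele-age distribution under
    any finite absorbing Markov chain, instantiated for a biallelic diploid
    Wright-Fisher model with selection, dominance and bidirectional mutation.
    The moments are obtained from a single sparse LU factorization of the
    transposed resolvent (I - Q)' followed by repeated triangular solves, with
    no matrix-matrix products. Also provides classical absorbing-chain
    summaries (absorption probabilities, conditional absorption and sojourn
    times), a Poisson prior over the founding copy number, a time-reversed
    chain Monte-Carlo validator, and the Kimura-Ohta neutral diffusion age as
    an independent baseline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    graphics,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
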