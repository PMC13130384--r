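Package: r2dt
Title: Reference-Dependent Decision-Theoretic Dose Finding for Phase I-II
    Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Design and simulation tools for Bayesian phase I-II dose-finding
    trials that select doses by maximising posterior expected utility.  The
    utility is a von Neumann-Morgenstern multi-attribute function built from
    reference-dependent power utilities for the probabilities of efficacy and
    toxicity, allowing loss aversion and distinct risk attitudes for gains
    and losses relative to clinically elicited reference points.  The package
    provides the utility functions and their degenerate linear special case,
    an independent logistic dose-response model with normal priors and an
    adaptive Metropolis posterior sampler, dose admissibility and
    utility-contour stopping rules, certainty-equivalent elicitation solvers
    for all utility parameters, and a trial simulator that reports operating
    characteristics (per-dose selection percentages, patients treated, and
    the proportion of trials stopping with no dose selected).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
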