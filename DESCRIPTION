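Package: dollomap
Title: Dollo Stochastic Character Mapping of Gene-Family Gain and Loss on Timetrees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps the birth and death of binary characters (such as microRNA
    families scored by presence/absence) onto a fixed time-calibrated phylogeny
    under the Dollo assumption of a single origin followed by irreversible loss.
    Gain and loss events are placed deterministically by parsimony and their
    times are sampled stochastically along branches, with replication providing
    Monte-Carlo confidence intervals for per-branch rates, per-time-bin rate
    series and root-to-tip lineage summaries.  Also provides maximum-likelihood
    estimation of global gain and loss rates under an asymmetric two-state
    Markov model with the root fixed to absence, marginal ancestral states,
    consistency-index homoplasy assessment, and a seeded simulator of
    presence/absence matrices with annotation-noise injection for validating
    every stage against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
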