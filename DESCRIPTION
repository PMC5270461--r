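Package: prognet
Title: Optimal Prognosis Classification for Boolean Gene Regulatory
    Networks under Mutation Uncertainty
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Models gene regulatory networks as Boolean networks with
    stochastic gene perturbation, computes their steady-state
    distributions, and designs optimal external control policies that
    minimize the long-run occupancy of undesirable (pathological) states
    via the average-cost occupation-measure program.  Builds uncertainty
    classes of mutated networks around a healthy reference network,
    assigns geometric mutation priors, partitions the class into four
    prognosis categories by treatability, and classifies a single
    observed gene activity profile with an exact optimal Bayesian
    classifier, including closed-form expected error and per-state
    posteriors.  Ships the mammalian cell-cycle and p53 stress-response
    networks as packaged fixtures and a generator for synthetic network
    studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
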