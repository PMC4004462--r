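Package: mlpip
Title: Multi-Level Protein Interaction Prediction with Logic-Constrained Kernel Machines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Collective prediction of protein-, domain- and residue-level
    physical interactions. Each level is modelled by a pairwise-kernel
    machine, and the three predictors are tied together by first-order
    logic consistency rules (e.g. two bound proteins must have at least
    one bound domain pair) compiled into continuous penalties via the
    product t-norm and the minimum t-norm residuum, including an
    n-existential quantifier for residue interfaces. Training follows a
    two-stage procedure: independent convex fits per level, then joint
    subgradient descent on the constrained objective with transductive
    enforcement on unlabeled pairs. Includes a hierarchically consistent
    synthetic data generator and leak-free cross-validation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    kernlab,
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
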