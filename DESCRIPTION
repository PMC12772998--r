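Package: metaforage
Title: Meta-Learning Analyses for a Depleting Spatial Bandit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulation and analysis tools for studying meta-learning in a
    three-patch, six-port spatial bandit with a reward depletion-repletion
    rule. Implements the task environment, a Beta-Bernoulli learner with a
    depletion factor and forgetting, a structured softmax choice model with
    maximum-likelihood and hierarchical Laplace-EM fitting, behavioral
    foraging metrics, synthetic Poisson spiking populations with
    multiplicative value gain on task-structure tuning, Poisson GLM encoding
    analyses with value-generality categorization, population state-space
    geometry, per-bin LASSO decoding of switch value with structured
    cross-validation, and decoded-value meta-learning metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
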