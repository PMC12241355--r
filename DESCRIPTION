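Package: rlwm
Title: Reinforcement Learning and Working Memory Mixture Modelling of
    Stimulus-Response Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits a mixture model of instrumental learning in
    which a capacity-limited, decaying working-memory store and an incremental
    reinforcement-learning system jointly drive choice. Provides generators for
    the block-structured stimulus-response task with varying set sizes, a
    delay-modulated mixture policy, maximum a posteriori fitting with grid
    search over integer working-memory capacity, parameter-recovery and
    posterior-predictive validation harnesses, and model-independent
    trial-level behavioural analyses, all runnable end to end on synthetic
    cohorts with dopamine-proxy covariate structure.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
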