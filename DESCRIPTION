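Package: gridsr
Title: Successor-Representation Reinforcement-Learning Agents in Gridworld
    Revaluation Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tabular reinforcement-learning agents built around the successor
    representation (SR), together with the classic gridworld revaluation tasks
    used to probe behavioural flexibility: latent learning, detour (transition
    revaluation), and policy revaluation. Implements five agent architectures
    (one-step-lookahead TD, SR-TD, SR-MB, SR-Dyna, Dyna-Q), closed-form and
    temporal-difference routes to the discounted occupancy matrix, experience
    replay with recency-weighted sampling, and an analysis layer that reduces
    simulated runs to median value maps, implied policies, and categorical
    agent-by-task flexibility verdicts against a value-iteration oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
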