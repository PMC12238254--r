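Package: orthoplanr
Title: Multi-Task Reinforcement Learning for Orthodontic-Orthognathic
    Treatment Planning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A clinical decision-support toolkit that formulates combined
    orthodontic-orthognathic therapy as a multi-objective Markov decision
    process. Provides a synthetic craniofacial patient simulator calibrated
    to published cohort statistics, a treatment environment with a
    saturating biomechanical response model, a multi-task soft actor-critic
    planner with shared and task-specific encoders and vector critics,
    explainability procedures (Shapley feature attribution, decision-tree
    policy surrogates, constrained counterfactuals, phase-decomposed
    trajectory explanations), and composite evaluation metrics including
    the Treatment Plan Quality Score, outcome-forecast accuracy, a
    normalized efficiency index, and a clinician confidence score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    rpart,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
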