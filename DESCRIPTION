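Package: kbrart
Title: Model-Based Reinforcement Learning for Response-Adaptive Radiotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision-support engine for knowledge-based response-adaptive
    radiotherapy (KBR-ART). Treatment adaptation is modelled as a one-step
    Markov decision process: a linear-quadratic-linear (LQL) transition
    function extrapolates mid-treatment generalized equivalent uniform dose
    (gEUD) to end of treatment for any candidate daily dose, graph neural
    network outcome estimators map a patient's multi-omics feature graph to
    tumor-control and normal-tissue-complication probabilities (including a
    generalized-logistic-guided double-GNN architecture that guarantees a
    monotone dose-response), and a double deep-Q-network trained by exhaustive
    planning over the artificial treatment environment recommends the optimal
    adaptive dose per fraction. Includes a ground-truth cohort simulator, a
    Wasserstein GAN with gradient penalty for tabular synthetic patients,
    Jensen-Shannon divergence diagnostics, ensemble uncertainty estimates, and
    evaluation against retrospective clinical decisions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    MASS,
    pROC,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
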