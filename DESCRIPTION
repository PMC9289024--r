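Package: sepsafe
Title: Safety Auditing and Safety-Constrained Retraining of Reinforcement
    Learning Sepsis Treatment Policies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for auditing the clinical safety of discretized-MDP
    reinforcement learning treatment policies for sepsis resuscitation.
    Implements four expert-defined hazard scenarios over blood pressure,
    central venous pressure, cumulative fluid balance and drug doses;
    two-proportion z-tests comparing human and AI unsafe-decision rates
    across blood-pressure threshold sweeps; gradient-boosting models with
    SHAP attribution of unsafe clinician behaviour; reward reshaping that
    penalises unsafe state-action instances and Q-learning retraining of a
    safety-constrained policy; and weighted importance sampling off-policy
    evaluation with stay-level bootstrap confidence bounds. A synthetic ICU
    sepsis cohort generator with known ground truth makes the full pipeline
    testable without access to restricted clinical databases.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
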