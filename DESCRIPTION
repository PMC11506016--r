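Package: valddm
Title: Hierarchical Drift-Diffusion Modelling of Moral and Emotional Valence Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing two-choice valence-evaluation reaction-time
    experiments with the drift-diffusion model. Provides numerically stable
    two-boundary Wiener first-passage-time densities (adaptive small-time and
    large-time expansions), closed-form absorption probabilities, an exact-seed
    diffusion simulator with bridge-crossing correction, and a hierarchical
    Bayesian estimator for a twelve-group design in which each valence group
    carries its own drift rate, boundary separation and non-decision time while
    all groups share a participant-level starting point. Inference is based on
    posterior difference distributions with a 95 percent directional rule and
    DIC model comparison between biased and unbiased starting-point variants.
    Also includes a synthetic-study generator (stimulus norming ratings,
    valence-group design, trial schedules, diffusion-generated responses with a
    response deadline) and the surrounding behavioral statistics: trial
    filtering, intensity transforms and word selection, repeated-measures
    ANOVA with partial eta squared, simple effects, paired t-tests with FDR
    correction, Cronbach's alpha, and power-based sample-size computation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
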