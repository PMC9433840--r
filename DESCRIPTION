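Package: cprlearn
Title: Reinforcement Learning Models of Common-Pool Resource Exploitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and model-based analysis of a common-pool resource
    (CPR) fishing game in which three players repeatedly harvest a
    replenishing fish stock. Provides the deterministic lake engine
    (catch-then-replenish dynamics with a capacity bound), a generator of
    surrogate opponent/migration streams calibrated to the task's
    pre-recorded behavior, a family of trial-by-trial reinforcement
    learning models with social-comparison, sustainability, inequity
    aversion and hybrid reinforcement terms, per-subject maximum
    likelihood fitting with bounded multi-start optimization,
    multi-criteria model comparison (BIC, Bayes-factor categories,
    McFadden pseudo-R-squared, balanced accuracy, random-effects Bayesian
    model selection with exceedance probabilities), model and parameter
    recovery analyses, behavioral summaries, posterior predictive checks
    and trial-wise reward prediction error export.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
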