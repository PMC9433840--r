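# cprlearn

Reinforcement learning models of common-pool resource (CPR)
exploitation.

Three players repeatedly harvest fish from a lake that replenishes by
×1.5 (rounded down) up to a capacity of 16; each player picks a net size
of 1, 2 or 3 fish per trial, a session ends when the lake is fished out
or after 8 trials, and every subject plays 16 sessions. The same
resource dynamics are framed either *socially* (two pre-recorded
opponents also fish) or *nonsocially* (the same number of fish
"migrates" away). The question the toolkit addresses is how people's
harvesting is shaped by social comparison versus sustainability
concerns, and it is aimed at computational cognitive modelers working on
social decision making and reinforcement learning.

The package provides, end to end:

* the deterministic lake engine (`cpr_config()`, `replenish()`,
  `allocate_catch()`, `run_session()`);
* surrogate opponent/migration streams calibrated to the task's
  pre-recorded behavior (`others_distribution()`, `sample_others_total()`,
  `split_total()`, `surrogate_stream()`);
* a family of trial-by-trial learning models sharing the softmax policy
  $p_t(i) \propto \exp[\beta Q_{t-1}(i)]$ and the fictive delta rule
  $Q_t(i) = Q_{t-1}(i) + \alpha\,[R_{i,t} - Q_{t-1}(i)]$ applied to all
  options, and differing in the reinforcement $R_{i,t}$: a uniform null
  baseline, plain Rescorla–Wagner ($R = i$), social comparison
  ($R = (1-\theta_s) i + \theta_s (i - m_t)$ with $m_t$ the opponents'
  mean payoff), sustainability
  ($R = (1-\theta_n) i - \theta_n |6 - i - F_t|$ with $F_t$ the
  outflow), Fehr–Schmidt inequity aversion, and a hybrid that
  interpolates between the social and sustainability comparisons with
  weight $\xi$ (`model_spec()`, `run_model()`);
* per-subject bounded multi-start maximum likelihood
  (`fit_subject()`, `fit_population()`);
* model comparison: BIC, Bayes-factor evidence bands, McFadden
  pseudo-R², balanced accuracy, and random-effects Bayesian model
  selection with exceedance probabilities (`evidence_matrix()`,
  `bms_random_effects()`, `balanced_accuracy()`);
* model and parameter recovery (`model_recovery()`,
  `parameter_recovery()`), behavioral summaries, posterior predictive
  checks and trial-wise prediction-error export
  (`depletion_reaction()`, `posterior_predictive_check()`,
  `export_rpe_regressors()`);
* a synthetic-cohort generator whose agents play the task through the
  same engine and update rules used in fitting (`simulate_agents()`),
  plus CSV/YAML/JSON i/o and a small command-line front end
  (`cpr_main()`, `inst/cli/cprlearn`).

The methods vignette (`vignettes/cpr-models.Rmd`) documents the model
family, the fitting and comparison machinery, the surrogate calibration,
and two structural identifiability results that any user of this family
should know about (the social-comparison weight is not identifiable from
choices, and the learning rate and inverse temperature trade off along a
sharp ridge).

## Worked example

Simulate six sustainability-minded agents in the nonsocial condition,
fit three competing models, and compare them:

```r
library(cprlearn)

d <- simulate_agents(model_spec("nonsocial"),
                     list(alpha = 0.4, beta = 2, theta_n = 0.6),
                     n_subjects = 6, condition = "nonsocial", seed = 42,
                     stock_conditional = TRUE)
session_length_summary(d)
#>   condition n_subjects mean_trials sd_trials
#> 1 nonsocial          6     6.15625 0.3552068

fits_null <- fit_population(model_spec("null"), d, seed = 42)
fits_rw   <- fit_population(model_spec("rw"), d, n_starts = 10, seed = 42)
fits_nso  <- fit_population(model_spec("nonsocial"), d, n_starts = 10, seed = 42)

ev <- evidence_matrix(list(fits_null, fits_rw, fits_nso))
round(colSums(ev$bic), 1)
#>      null        rw nonsocial
#>    1326.1    1147.7    1131.8

bms <- bms_random_effects(ev, n_mc_samples = 1e5, seed = 42)
round(bms$exceedance_probabilities, 3)
#>      null        rw nonsocial
#>     0.019     0.214     0.767

round(1 - colSums(ev$loglik) / sum(ev$loglik[, "null"]), 3)
#>      null        rw nonsocial
#>     0.000     0.159     0.192
```

The agents deplete the lake in about 6.2 trials per session on average.
The generating (nonsocial) model wins the comparison: lowest aggregate
BIC, exceedance probability 0.77 that it is the most frequent model in
the group, and the highest McFadden pseudo-R². Its signature behavioral
prediction also shows up in the simulated choices:

```r
dr <- depletion_reaction(d)
round(mean(dr$difference, na.rm = TRUE), 3)
#> [1] -0.59
```

After a large migration (6 fish), sustainability-driven agents *reduce*
their next catch by about 0.6 net sizes relative to trials following a
moderate decrease — a preservation reaction, the opposite of the
escalation that social comparison produces after opponents overexploit.

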