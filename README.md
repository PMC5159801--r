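# avrecal

Simulation and analysis of **action-contingent audio-visual temporal
recalibration** experiments based on simultaneity judgments.

After repeated exposure to a fixed lag between a sound and a flash, the
point of subjective simultaneity (PSS) shifts toward the adapted lag. In
the paradigm this package models, each of two voluntary actions produces
its own lagged audio-visual pair during learning (sound 234 ms before the
flash for one action, 234 ms after for the other); at test, actions produce
either their learned ("predicted") or the other action's ("unpredicted")
pair at one of 13 SOAs, and the question is whether recalibration is
conditional on action-outcome prediction. `avrecal` is for researchers who
want to simulate this design end to end — power analysis, parameter
recovery, analysis-pipeline validation — without collecting data.

## What it computes

The probability of a "simultaneous" response at SOA $x$ is a scaled
Gaussian

$$p(x) = \lambda + s\,\exp\!\left(-\tfrac{(x-\alpha)^2}{2\sigma^2}\right),$$

with PSS $\alpha$ (positive = sound must follow the flash), temporal
sensitivity $\sigma$, amplitude $s$, and optional lapse floor $\lambda$
(default 0). Fitting minimises the repetition-weighted squared error
$\sum_i w_i(\hat p_i - p(x_i))^2$ with $w_i$ the per-SOA presentation count
(8…20…8 across the 13 SOAs; 176 trials per condition, 704 per subject).
Cohort inference is the 2×2 within-subject ANOVA on PSS (adaptation order ×
outcome predictedness) with partial eta squared
$\eta_p^2 = F\,df_1/(F\,df_1+df_2)$, paired/one-sample t-tests with
$d_z = t/\sqrt n$, and achieved power via the noncentral F distribution
with $\lambda = n\,\eta_p^2/(1-\eta_p^2)$.

Modules:

- **schedule** — `design_config()`, `assign_counterbalancing()`,
  `build_learning_schedule()`, `build_test_schedule()`: deterministic,
  seeded trial schedules with counterbalancing and catch trials.
- **observer** — `population_spec()`, `make_population()`,
  `simulate_responses()`, `aggregate_responses()`, `simulate_cohort()`:
  the generative observer and cohort simulator.
- **psychfit** — `weighted_sse()`, `fit_gaussian()`, `fit_all()`,
  `apply_exclusion()`: bounded multi-start weighted least squares, weighted
  r², subject exclusion.
- **infer** — `rm_anova_2x2()`, `paired_t()`, `one_sample_t()`,
  `partial_eta_sq()`, `cohens_dz()`, `achieved_power()`,
  `interaction_equals_t()`.
- **pipeline** — `run_config()`, `run_pipeline()`,
  `reproduce_experiment()`, `recover_pss()`, CSV/JSON I/O, a diagnostic
  plot, and a thin CLI at `inst/cli/avrecal.R` (subcommands `simulate`,
  `fit`, `analyze`, `run`, `reproduce`).

## Worked example

```r
library(avrecal)
report <- run_pipeline(run_config(experiment_mode = "action",
                                  n_subjects = 15, seed = 1))
print(report)
#> <stat_report> action mode; 15 of 15 subjects analysed
#>   sound-first/predicted      mean PSS =   26.3 ms (SD  10.1), mean r^2 = 0.85
#>   sound-first/unpredicted    mean PSS =   41.2 ms (SD  16.7), mean r^2 = 0.82
#>   sound-second/predicted     mean PSS =   41.8 ms (SD  18.7), mean r^2 = 0.84
#>   sound-second/unpredicted   mean PSS =   24.2 ms (SD  17.1), mean r^2 = 0.82
#>   adaptation_order   F(1,14) =  0.017, p = 0.897, partial eta^2 = 0.001
#>   outcome_predicted  F(1,14) =  0.166, p = 0.690, partial eta^2 = 0.012
#>   interaction        F(1,14) = 23.768, p < 0.001, partial eta^2 = 0.629
#>   adaptation effect (predicted pairs): 15.5 ms; achieved power 0.997
```

This 15-subject synthetic cohort was generated under the effect regime
(predicted-pair generative PSS means 23 and 45 ms, i.e. a 22 ms adaptation
effect; null separation for unpredicted pairs up to a small opposite
pattern). The fitted predicted-pair means (26.3 and 41.8 ms) straddle the
generative values within sampling noise, the order × predictedness
interaction is significant while both main effects are null — the signature
of action-contingent recalibration — and the recovered adaptation effect
(15.5 ms here) fluctuates around 22 ms across cohorts of this size.
`reproduce_experiment(2, ...)` and `reproduce_experiment(3, ...)` run the
cue-contingent control regimes, where the interaction rejection rate stays
near the nominal 5%.

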