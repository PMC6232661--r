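# hfacsbn

Needlestick and sharps injuries (NSIs) are among the most serious
occupational hazards faced by hospital nurses — percutaneous injuries that
can transmit hepatitis B/C and HIV.  They are multifactorial: management
commitment, staffing, supervision, scheduling, fatigue and motivation all
contribute, at different organizational levels.  `hfacsbn` is an R package
for analysing NSI risk with a **discrete Bayesian network whose structure
is fixed by the HFACS framework** (Human Factors Analysis and
Classification System): organizational influences (level 4) → unsafe
supervision (level 3) → preconditions for unsafe acts (level 2) → the NSI
outcome.  Two structural assumptions — no edges within a level, complete
connection between adjacent levels — turn the framework into a 12-node,
32-edge network with 1,358 CPT entries whose joint distribution
factorizes as

    P(x_1, ..., x_12) = prod_v P(x_v | parents(x_v))

and all reasoning is exact belief updating, `p(A|B) = p(B|A) p(A) / p(B)`.

The package is written for occupational-safety researchers who want the
whole published workflow as tested, reusable code:

* **Questionnaire ingestion** — Likert scale scoring, Cronbach alpha,
  straight-liner filtering, discretization into the study's ordered
  states (`preprocess_questionnaire()`, `split_train_test()`);
* **Learning** — EM estimation of all CPTs with missing answers
  marginalized exactly (`em_fit()` / `hfacs_bn_fit()`, returning a
  classed model with `print`/`summary`/`coef`/`logLik`/`predict`/
  `simulate`/`plot` methods);
* **Exact inference** — variable elimination (`bn_posterior()`) plus an
  independent full-enumeration oracle (`enumerate_posterior()`);
* **Validation** — error rate/confusion matrix, logarithmic loss,
  quadratic (Brier) loss, spherical payoff (`evaluate_model()`);
* **Sensitivity & interventions** — mutual information and
  predictive-reasoning best/worst scans with the published sensitivity
  index `100 (best - worst) / worst`, and what-if evidence scenarios
  (`sensitivity_analysis()`, `evaluate_intervention()`);
* **A calibrated synthetic study** — the original hospital data are not
  public, so `make_study()` generates item-level questionnaires from a
  ground-truth network calibrated by exact inference to the published
  marginals (27.9% NSI-yes, 55.4% staffing sufficient, 75.8% procedures
  available, 43.2% motivated), with realistic reliabilities, missing
  answers and planted straight-liners.

## Worked example

```r
library(hfacsbn)

study <- make_study(generator_config(seed = 1))   # 408 questionnaires
print(study$preprocess)
#> Questionnaire preprocessing
#>   received 408, discarded 14 (straight-lining), retained 394
#>   Cronbach alpha by scale:
#>     management_commitment  0.87
#>     staffing               0.86
#>     ...

fit <- hfacs_bn_fit(study$train)                  # EM on 343 records
fit
#> HFACS Bayesian network (12 nodes, 32 edges, 1358 CPT entries)
#>   fitted by EM on 343 records: log-likelihood -3621.10 after 10 iteration(s)

evaluate_model(fit, study$test)
#> Model performance on 49 test cases
#>   Index                     Value   Range
#>   Total error rate (%)      28.57   0-100 (lower is better)
#>   Logarithmic loss           0.61   0-Inf (lower is better)
#>   Quadratic loss             0.41   0-2   (lower is better)
#>   Spherical payoff           0.77   0-1   (higher is better)

evaluate_intervention(fit, list(safety_motivation = "good"))
#> Intervention (evidence mode)
#>   evidence: safety_motivation = good
#>   P(favourable outcome): 71.4% (baseline 66.7%, change +4.7 pp)
#>   predicted NSI rate:    28.6%
```

The preprocessing report shows the study bookkeeping (408 received, 14
straight-liners discarded, 394 retained, of which 343 train and 50 test);
the performance table is the four standard indices on the held-out cases
(one test record had a missing outcome and is skipped); and the
intervention line reads: forcing safety motivation to its best state
raises the posterior of "no NSI in 3 months" from 66.7% to 71.4%, i.e. a
predicted injury rate of 28.6% under that scenario.  `sensitivity_analysis(fit)`
prints the full 11-predictor ranking by level, with the mutual-information
column in bits and as a percent of outcome entropy.

A command-line wrapper covering the same workflow
(`simulate`/`preprocess`/`fit`/`evaluate`/`sensitivity`/`intervene`/`report`)
is installed at `inst/scripts/hfacsbn` and is also callable in-process via
`hfacs_cli()`.

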