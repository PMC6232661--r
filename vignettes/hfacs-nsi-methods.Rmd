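---
title: "Modelling needlestick and sharps injuries with an HFACS-structured Bayesian network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling needlestick and sharps injuries with an HFACS-structured Bayesian network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hfacsbn)
```

## The model

Needlestick and sharps injuries (NSIs) among hospital nurses are
multifactorial: organizational conditions shape supervision, supervision
shapes the working conditions of individual nurses, and those conditions
shape the injury risk.  `hfacsbn` encodes this causal cascade as a discrete
Bayesian network whose qualitative structure is fixed a priori by the
Human Factors Analysis and Classification System (HFACS), a four-level
accident-causation framework:

* **Level 4 — organizational influences**: management commitment to
  safety, staffing, availability of safe work procedures;
* **Level 3 — unsafe supervision**: night shifts per month, working hours
  per week, supervisors' attitude toward safety, safety training;
* **Level 2 — preconditions for unsafe acts**: fatigue, teamwork,
  physical environment, safety motivation;
* **Level 1 — outcome**: an NSI in the last three months (yes/no).

Two structural assumptions turn the framework into a graph: variables
within a level are not directly connected, and *every* variable of a level
is a parent of *every* variable in the immediately lower level.  With the
twelve study variables this gives 32 edges and 1,358 conditional
probability table (CPT) entries; the largest single table belongs to a
three-state level-2 node with four three-state parents, $3^5 = 243$
entries, which is also the usual rule-of-thumb minimum for the number of
training cases.

The joint distribution factorizes as
$P(x_1,\dots,x_{12}) = \prod_v P(x_v \mid \mathrm{pa}(x_v))$,
and all reasoning in the package — prediction, sensitivity, intervention —
is belief updating $p(A \mid B) = p(B \mid A)\,p(A)/p(B)$ carried out
exactly.

### Why two inference engines

`bn_posterior()` implements sum–product variable elimination (min-fill
ordering, ties broken by canonical variable order for reproducibility;
on a 12-node network any order is fast).  `enumerate_posterior()` is a
deliberately naive oracle that scores all 236,196 full assignments by the
chain rule and sums the consistent cells.  The two code paths share
nothing beyond the CPT container, so their agreement (asserted to
$10^{-9}$ over batches of seeded random models in the test suite) is a
meaningful correctness check rather than a tautology.

Evidence with zero probability raises a dedicated condition
(`bn_impossible_evidence`) instead of returning `NaN`s: during EM and
prediction it matters whether a configuration is impossible under the
model or the code is broken.

## Questionnaire ingestion

Each multi-item scale (five items for management commitment, four for the
others — 33 Likert items in total) is scored by the mean of its answered
items; a score is treated as missing when fewer than half the items were
answered, and residual missingness is left to EM rather than imputed.
Scale scores in $[1,5]$ are discretized into three equal intervals,
$[1, 7/3)$, $[7/3, 11/3)$, $[11/3, 5]$ — left-closed so that the mapping
is total and unambiguous, with the top interval closed at 5.  Working
hours per week use the cut points $<45$ / $45$–$55$ / $>55$ and night
shifts per month $\le 8$ / $9$–$11$ / $\ge 12$.  Passing an already
discretized label back through `discretize_value()` is an error by
design: silent double-discretization is a classic pipeline bug.

Respondents who answered every Likert item with one constant value are
flagged as straight-liners and discarded.  Zero response variance over a
complete questionnaire is the narrowest defensible reading of a
"systematic response pattern"; alternating patterns are deliberately not
chased, because any broader rule risks discarding genuine responders.

Reliability is summarized by Cronbach's alpha,
$\alpha = \frac{k}{k-1}\bigl(1 - \sum_i s_i^2 / s_T^2\bigr)$, computed on
listwise-complete rows.  A zero-variance total score makes $\alpha$
undefined and is signalled as an error, not returned as `NaN`.

The train/test split mirrors the study bookkeeping: with at least 393
retained records the fixed sizes 343 (training) and 50 (test) are drawn at
random under a caller-supplied seed and any surplus is reported as unused
(the source study itself retains 394 records but uses 393); smaller
datasets are split in the same 343:50 proportion, e.g. 100 records give
87/13.

## Parameter learning

CPTs are estimated by expectation–maximization.  The E-step enumerates,
per record, the completions of its missing values and weights them by
their exact probability under the current parameters; the M-step
re-estimates every CPT row as smoothed relative frequencies
$(c + \lambda)/(N + \lambda k)$ with pseudocount $\lambda = 1$ by default.
The smoothing choice is pragmatic: a single unsmoothed zero in a CPT makes
logarithmic-loss scoring undefined on any test case that hits it.  With
$\lambda > 0$ the quantity EM is guaranteed to ascend is the *penalized*
likelihood (log-likelihood plus the Dirichlet log-prior), so fitted models
record both `trace` (observed-data log-likelihood) and `objective_trace`
(the penalized objective); both are asserted non-decreasing in the test
suite.  Convergence is declared when the relative change in observed-data
log-likelihood falls below $10^{-6}$, with a cap of 500 iterations —
conservative defaults for a 12-node network that typically converges in
about ten.

Records with no observed value carry no information and are dropped;
records missing more than eight of the twelve variables are also dropped
to bound the completion expansion ($3^8 = 6561$ rows), with a warning in
both cases.  Records missing only the outcome are perfectly usable and are
routinely retained.

## The synthetic study

The raw hospital questionnaires behind the published analysis are not
public, so the package carries a first-class generator that emulates the
study conditions and closes the loop for every stage of the pipeline.

`make_ground_truth()` fills the HFACS structure with monotone
ordered-logit CPTs: each state of each variable carries a favourability
score (0 = worst for safety, 1 = best), and the probability of favourable
child states increases with the weighted mean favourability of the parent
states.  Exhaustive monotonicity — flipping any single parent from worst
to best never decreases the child's expected favourability — is asserted
in the tests.  Root priors and two logit shifts are then calibrated
against *exact inference* (bisection, no sampling) until the model
marginals reproduce the study's published figures: 27.9% NSI-yes, 55.4%
staffing sufficient (split equally between the moderate and good states),
75.8% procedures available, 43.2% well motivated.

The effect strengths default to 1.6 (level 4 → 3 and 3 → 2) and 3.0
(level 2 → outcome), with the outcome weighting motivation highest
(1.4) ahead of fatigue (1.2), physical environment (1.1) and teamwork
(0.8).  These values were chosen so that the generating model behaves like
the published fitted model: single-predictor best/worst posteriors of
$P(\mathrm{NSI} = \mathrm{no})$ span roughly 60–80%, and forcing safety
motivation to its best state drops the predicted NSI rate to about 20%,
the scale of the published intervention analysis.  One consequence worth
stating plainly: with the published marginal (27.9% yes) and
sensitivities of this size, the Bayes error of *any* such model is close
to the majority-class rate, so a 50-case test-set error rate fluctuates
around that baseline — a small printed error rate should be read as one
draw, not as proof of high discriminability.

`sample_respondents()` draws each respondent's twelve latent states by
ancestral sampling and then emulates the instrument on top: Likert items
are drawn around state-specific centres $3 \pm 1.3$ (outer states) and 3
(middle state) plus a shared respondent trait (sd 0.1) and per-item noise
(sd 0.82), rounded and clipped to 1–5; scheduling answers are drawn
uniformly inside each state's defining interval (hours capped at 84,
night shifts at 16); missing answers are injected completely at random
(2% per answer by default); and 14 of 408 respondents are overwritten as
straight-liners so the quality filter has true positives to find.  The
centre spread and noise values were tuned once, at generator-design time,
so that per-scale Cronbach alphas land inside the published 0.76–0.88
band while the re-discretized scale means still agree with the latent
state for over 90% of respondents; centres one Likert point apart cannot
satisfy both at four items per scale, which is why the spread is a
parameter.  A narrower spread or a larger `item_sd` degrades reliability
smoothly (asserted over a noise grid in the tests).

What the generator does *not* emulate: hospital-level clustering (a
`hospital` column is emitted but unused, as in the source analysis),
respondent demographics, non-random missingness, and any questionnaire
misbehaviour beyond straight-lining.  Passing tests on synthetic data
therefore demonstrate that the pipeline recovers a model of this family
from data of this structure — not that the HFACS assumptions hold in any
particular hospital.

## Validation metrics

Model performance on held-out cases is summarized exactly as in the
source analysis: a confusion matrix with its total error rate (predicted
label = argmax state; a 50/50 tie is called "yes" as the conservative
choice for a safety outcome), logarithmic loss $-\ln P_c$ (natural log by
default, base configurable), quadratic loss $1 - 2P_c + \sum_j P_j^2$
(range 0–2), and spherical payoff $P_c / \sqrt{\sum_j P_j^2}$ (range 0–1,
higher better), each averaged over cases.  Published prose that swaps the
spherical-payoff and quadratic-loss ranges is resolved in favour of the
internally consistent table form.

## Sensitivity and interventions

`sensitivity_analysis()` ranks the eleven predictors within their HFACS
level by two complementary measures.  *Predictive reasoning*: condition
on each state of a predictor, read off the posterior percent of
"NSI = no", and report the worst and best states; the sensitivity index
is the relative percent increase worst→best,
$100\,(\mathrm{best}-\mathrm{worst})/\mathrm{worst}$.  This formula is
reverse-engineered: it is the only candidate that reproduces, to one
decimal, the full published 11-row table from its own worst/best columns
(`nsi_reference_sensitivity()` ships those rows, and the test suite
asserts all eleven).  *Mutual information*:
$\sum_{x,y} P(x,y)\log_2 \frac{P(x,y)}{P(x)P(y)}$ bits, with the pairwise
joint obtained by exact inference; the parenthesized percent is
$100\,\mathrm{MI}/H(\mathrm{outcome})$, the reading consistent with the
published percentages.

`evaluate_intervention()` treats an intervention as evidence —
observational conditioning, which is what predictive reasoning on this
network means — and reports the complement of the favourable posterior as
the predicted NSI rate (a best-state posterior of 79.5% implies a rate of
20.5%).  A do-style mode (`mode = "do"`, CPT replaced by a point mass,
severing the node from its parents) is available for comparison but off
by default; on this network the two differ only through the conditioning
information that evidence carries upstream.

## Numerical and testing choices

Parent configurations are enumerated in one canonical order everywhere —
mixed-radix over the ordered parent list, last parent fastest — so CPT
rows, JSON output and the XMLBIF export are byte-stable.  Structure
construction is deterministic; sampling is reproducible from a single
seed per configuration.

The test suite and the acceptance script size their simulations to run on
one CPU in a few minutes: oracle-equivalence batches use 12–100 random
models, reliability checks use cohorts of 1,500–10,000 respondents, and
parameter-recovery runs use 5,000 cases with 20% missingness.  One
statistical fact discovered while building the recovery tests deserves
record: for CPT rows whose parent configuration has an expected count
around 50, the binomial noise floor of *any* estimator is roughly
$\pm 0.2$ at mid-range probabilities, so recovery is asserted on a fixed
set of strongly supported rows (and as a decreasing trend in $n$) rather
than as a uniform tight bound at count 50.

## Limitations

The network structure is assumed, not learned; the model cannot detect
violations of the two HFACS assumptions (e.g. direct links from staffing
to fatigue that skip level 3).  Interventions are conditioning, not
causal surgery, and inherit every causal caveat of the underlying
framework.  The generator's ordered-logit tables are one convenient
monotone family; real questionnaire data need not be monotone in this
sense.  And the published sensitivity table is reproduced as arithmetic
on its printed columns — the hospital dataset itself is not available to
re-derive it.
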