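---
title: "Modeling temporal credit assignment under delayed, aggregated feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling temporal credit assignment under delayed, aggregated feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(credassign)
library(dplyr)
```

## The problem

When a reward arrives two trials after the action that earned it, and the
screen may additionally aggregate it with the current trial's immediate
reward, a learner has to decide *which past action to credit*. `credassign`
implements a complete simulation-and-analysis pipeline for this temporal
credit-assignment problem: the two-alternative task environment, two
learning strategies and their hybrid, penalized model fitting, recovery
studies that validate the fitting machinery, and the behavioral signature
analyses that distinguish the strategies.

The task: 8 stimuli, 4 paying immediately and 4 paying two trials later,
with starting rewards 4, 1, -1, -4 in each delay class. Rewards drift as
integer-rounded Gaussian random walks, so learning never saturates. Every
one of the 28 unordered stimulus pairs is offered 12 times (336 trials per
session). Feedback is rendered either *conjoint* (one summed total: high
information uncertainty) or *disjoint* (separate immediate and delayed
boxes: low uncertainty); each simulated participant plays one session per
condition in counterbalanced order.

## The two strategies

**Retrospective: replacing eligibility trace.** A single prediction error
against the displayed total,

$$\delta_t = r_t - v_t(a_t),$$

is broadcast back over the recent choice sequence through per-action traces
$e_t(a)$: the chosen action's trace is reset to 1 (replacing rule, which
bounds traces in $[0,1]$), all others decay by $\lambda_{elg}$, and every
action updates $v(a) \mathrel{+}= \alpha_{elg}\,\delta_t\,e_t(a)$. Credit
therefore falls off geometrically with recency, including onto the
systematically irrelevant one-trial-back choice.

**Prospective: delay-indexed tabular values.** The learner represents
*when* each stimulus pays, holding $Q(d, a)$ for delay slots $d \in \{0,
2\}$ only (the one-trial lag has no slot, because no stimulus pays at lag
1). Two prediction errors update the current choice at $d = 0$ and the
choice from two trials back at $d = 2$; only the delayed slot is discounted
by $\lambda_{tab}$. In conjoint both errors compare against the same
displayed total; in disjoint each compares against its own displayed
component. By default an absent component counts as a zero reward and still
drives an update (the prediction errors are computed unconditionally);
`skip_absent = TRUE` implements the alternative reading in which only
delivered components update.

**Decision rule.** Both value functions are locally z-normalized (below)
and combined in a softmax over the two offered options with non-negative
strategy weights:

$$\pi_t(a) \propto \exp\!\big[\beta_{elg}\, z(v_t(a)) + \beta_{tab}\,
z(\textstyle\sum_d Q_t(d,a))\big].$$

Setting either weight to zero reduces the hybrid exactly to the other
single-strategy model — the test suite asserts this identity to $10^{-10}$
relative error. Shared-parameter hybrids (`hybrid_1L`: one learning rate;
`hybrid_1D`: one learning and one decay rate) are available as variants.

## Local value normalization

Because the walks and the two feedback conditions put values on different
scales, values entering the softmax are z-scored against the recent history
of the same value function: mean and standard deviation are pooled over all
8 entries of the decision-time value vectors from the previous `window`
trials (default 5; 0 disables scaling; `Inf` pools over the whole preceding
task). Design choices that fix the remaining degrees of freedom:

* each strategy is normalized against its own history, since the softmax
  applies $z(\cdot)$ inside each weight's term;
* population (divide-by-$n$) variance convention;
* on the first trial the buffer is empty and raw values pass through
  (means 0, spread 1 — the softmax is shift-tolerant, so this is inert);
* a zero-spread buffer removes the mean only.

A consequence worth knowing: choice probabilities are invariant to positive
rescaling of all rewards on trials whose buffers have non-degenerate
spread (a property test covers this).

## Degenerate inputs and bookkeeping rules

* Trial indices are 0-based; the delayed reward earned at trial $t$ is the
  walk's delivered value at $t$ and arrives at $t + 2$ regardless of
  intervening omissions (the queue is indexed by trial, not by response).
* Rounding of delivered rewards is half-away-from-zero, symmetric around
  the negative start values; the latent walk accumulates unrounded.
* Omitted responses contribute no likelihood term and no value update;
  eligibility traces still decay (time passes). Simulated agents always
  respond, so this matters only for imported data.
* A probability floor of $10^{-12}$ inside the log keeps the fitting
  objective finite during optimizer exploration.

## Fitting

Each session is fitted separately per condition by minimizing
$\mathrm{nll}(\theta) - \sum \log p(\theta)$ with weakly-informative
penalty priors — Gamma(1.25, scale 1) on each strategy weight,
Beta(1.25, 1.25) on each rate — which vanish at the rate bounds, keeping
estimates strictly interior. Bounds are $[10^{-6}, 1 - 10^{-6}]$ for rates
and $[0, 20]$ for weights (20 saturates a two-option softmax on z-scored
values). AIC, BIC and pseudo-$R^2$ (against the uniform-choice null over
responded trials) are computed from the *unpenalized* likelihood at the
optimum; `penalized_metrics = TRUE` exposes the alternative.

The optimizer is a rand/1/bin differential-evolution routine
(`de_optimize()`): population $15 \times$ dimension, mutation factor 0.8,
crossover 0.9, at most 300 generations, convergence declared after 25
generations with relative improvement below $10^{-8}$, reflecting bounds,
fully seeded so refits are bit-reproducible. One fitted consequence of the
penalty worth knowing: because the weight prior vanishes at 0, a hybrid
MAP fit keeps both weights slightly positive, so its raw likelihood can
sit marginally above a single-strategy optimum even though the likelihood
itself nests exactly.

## The synthetic-data generator

There is no deposited behavioral dataset, so `generate_study()` is the
stand-in for raw data and is itself first-class, tested code. Generative
parameters are drawn per session from Beta(1, 2) for learning rates,
Gamma(shape 3, scale 1) for strategy weights, and Beta(2, 3) for decay
rates (shape–scale convention). `beta_min` truncates the weight draw from
below when informative, low-noise choosers are needed — recovery studies
use `beta_min = 2`. Three reward walks are built per study; each session
independently draws one, so about a third of participants see the same
walk twice. Condition order alternates deterministically, giving an exact
half-and-half counterbalance.

What the generator deliberately does **not** emulate: response times and
the 15-second response window, fatigue or order carry-over, perseveration,
working memory, and asymmetric learning — the agents are stationary
softmax learners. Passing tests therefore certify the machinery
(likelihoods, optimizers, event extraction, regressions) on data whose
generating process is known, not that human data obey these models.

## Validation studies

**Parameter recovery** (`run_parameter_recovery()`): draw parameters,
simulate a session per condition, refit the same variant, correlate. The
full-scale design uses 300 datasets; the test suite and acceptance script
run 25 draws × 2 conditions per variant, which is where the correlations
quoted in the README come from. With informative weights
(`beta_min = 2`), strategy weights and decay rates recover with $r > 0.85$
at 336 trials. The tabular learning rate is flagged in the recovery report
rather than gated in tests, since its recovery is design-dependent.

**Model recovery** (`run_model_recovery()`): simulate from each variant,
fit all variants, tabulate which wins by AIC and by BIC (ties go to the
simpler model). Both criteria are reported; the suite asserts only
above-chance diagonals, making no claim about which criterion is better —
that is an empirical matter that varies with the design.

## Behavioral signatures

* `behavioral_metrics()`: proportion of optimal choices (ties count as
  optimal — no wrong answer exists on tied trials) and mean obtained
  walk reward.
* `extract_stay_events()` and `stay_signature_regression()`: delayed
  choices whose stimulus is offered again exactly three trials later
  (the "exactly $t+3$" reading), expanded into a condition × time × reward
  logistic regression on staying. Feedback valence is coded from what was
  displayed: strictly positive is `"+"`. The 2F valence uses the feedback
  that actually reports the origin choice's delayed reward (the delayed
  box at $t+2$ in disjoint, the total at $t+2$ in conjoint). For 0F we
  use the displayed total at the origin trial in both conditions: coding
  disjoint 0F from the immediate box alone would make the factor constant
  (a delayed-class choice leaves that box empty), collapsing the
  regression's design; the component reading remains available as
  `disjoint_0F = "component"`, and the conjoint component reading as
  `conjoint_valence = "component"`.
* The regressions are pooled fixed-effects logistic fits — a deliberate
  simplification of random-slope multilevel estimation, which is out of
  scope here; with simulated stationary agents the pooled and multilevel
  fixed effects estimate the same quantities.
* `credit_gradient()`: the one-step value change applied to the options
  chosen at lags 0–3, over windows of four distinct responded choices,
  split by prediction-error valence. The eligibility gradient decays
  geometrically with ratio $\lambda_{elg}$ (exact, per valence group); the
  tabular gradient is exactly zero at lags 1 and 3.
* `pairtype_accuracy()`: model-vs-observed choice agreement split by pair
  composition (delayed/delayed, immediate/immediate, mixed: 72, 72 and 192
  trials per session).
* `parameter_condition_tests()`: paired t contrasts of fitted parameters
  across conditions with Cohen's *d*; zero-variance contrasts are flagged
  as degenerate, not tested.

## Problem sizes and reproducibility

All randomness flows from explicit integer seeds through `ca_seed()`, a
label-hash splitter that gives every component (walk, schedule, draw, fit)
an independent, reproducible child seed; rerunning any function with the
same seed reproduces its output exactly. The shipped test-suite and
acceptance-script problem sizes — 25 recovery draws per condition, 15
model-recovery simulations per generating variant, studies of 2–10 agents
— were chosen as the smallest designs whose statistics are stable across
seeds; the full-scale designs (300 recovery datasets, 25 posterior
iterations over a whole cohort) run through the same code paths by
changing the size arguments.

## A worked pipeline

```{r pipeline, eval = FALSE}
study <- generate_study(10, variant = "hybrid", beta_min = 2, seed = 42)

fits_e <- fit_study(study$sessions, "eligibility", seed = 42)
fits_t <- fit_study(study$sessions, "tabular", seed = 42)
fits_h <- fit_study(study$sessions, "hybrid", seed = 42)
compare_models(bind_rows(fits_e[-ncol(fits_e)], fits_t[-ncol(fits_t)],
                         fits_h[-ncol(fits_h)]))

events <- extract_stay_events(study$sessions, study$stimset)
stay_signature_regression(events)$cells

rec <- run_parameter_recovery("eligibility", n_datasets = 25,
                              beta_min = 2, seed = 42)
autoplot(rec)
```

## Known limitations

* The fixed-effects signature regressions understate between-subject
  heterogeneity present in real cohorts; subject-clustered standard errors
  or a multilevel package should be layered on for human data.
* Recovery quality degrades sharply for uninformative agents (weights near
  0), as all models collapse toward the coin-flip likelihood; recovery
  claims here are conditional on `beta_min`.
* The tabular learning rate is weakly identified in this design; its
  condition contrasts should be interpreted with its recovery correlation
  in hand.
* `N(0, 0.25)`-style walk notation is read as a variance (step sd 0.5);
  if the spread reading is intended, pass `step_scale = 0.25`.
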