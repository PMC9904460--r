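---
title: "A three-state Markov cohort model for treatment cost-effectiveness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A three-state Markov cohort model for treatment cost-effectiveness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ceamarkov)
```

## The decision problem

Two first-line treatments for metastatic renal cell carcinoma — anlotinib
and sunitinib — showed near-identical efficacy in a head-to-head phase II
trial (median PFS 17.5 vs 16.6 months, median OS 30.9 vs 30.5 months) but
very different prices and toxicity (grade ≥ 3 adverse-event incidence 28.9 %
vs 55.8 %). When clinical effects are this close, the economic comparison
drives the recommendation. This package implements the standard
decision-analytic machinery for that question: a discrete-time Markov cohort
model with three health states, discounted reward accrual, incremental
cost-effectiveness statistics, and deterministic plus probabilistic
sensitivity analysis.

## Model structure and assumptions

The cohort starts entirely in the **stable** state (progression-free, on
first-line treatment). Each one-month cycle a stable patient may progress,
die, or remain stable; a **progressive** patient (on subsequent treatment)
may die or remain; **dead** is absorbing with zero cost and utility. The
per-cycle transition matrix is

```
stable       [ 1 − p_sp − p_sd    p_sp       p_sd ]
progressive  [ 0                  1 − p_pd   p_pd ]
dead         [ 0                  0          1    ]
```

Transition probabilities derive from median times-to-event under a
constant-hazard (exponential) assumption: `p = 1 − 0.5^(cycle/median)`.
`p_sp` uses the median PFS, `p_sd` the median OS, and `p_pd` the median
post-progression interval, *defined* as median OS − median PFS. Two
consequences of that definition are worth making explicit:

* Deriving `p_sd` from the OS median while `p_sp` comes from the PFS median
  mildly double-counts death risk in the stable state. We keep it because
  it is the parameterisation the published probability set encodes, and
  fidelity to those printed parameters matters more here than actuarial
  purity.
* The "median OS" of this framework is an additive construct
  (median PFS + median post-progression interval). The sum of two
  exponential phases is hypoexponential, so the raw sample median of OS in
  patient-level data exceeds that sum. `estimate_summary()` therefore
  estimates `median_os` as `median(PFS) + median(OS − PFS)` — the only
  estimator whose derived transition probabilities recover the generating
  ones — and reports the raw sample median alongside as `median_os_raw`.

The horizon is 120 monthly cycles (10 years): with the reference transition
probabilities more than 99 % of the cohort is dead at termination, so this
is effectively a lifetime horizon.

## Reward accrual conventions

Markov cost-effectiveness results are sensitive to bookkeeping conventions
that published reports rarely state. All of them are explicit,
switch-selectable settings here; the defaults are the combination under
which the package reproduces the reference analysis most closely (all six
base-case aggregates within 1 %).

* **State counting** (`counting`): rewards accrue on the state occupied at
  the *beginning* of each cycle (`"start"`, the default, with discount
  exponent equal to the elapsed cycles; this is the stage-reward behaviour
  of mainstream Markov modelling software), at the end (`"end"`), or as the
  average of the two (`"half"`, the half-cycle correction).
* **Adverse-event disutility** (`ae_disutility_mode`): the grade ≥ 3
  adverse-event disutility (0.157, weighted by the arm's incidence) is
  charged per month spent in the stable state, discounted (`"per_cycle"`,
  the default — toxicity management accompanies active first-line
  treatment); alternatives are a single undiscounted one-month lump at
  model entry (`"one_time"`) or `"none"`. Under the default the QALY
  difference between arms (0.055) is dominated by this term, which is
  exactly the behaviour the printed per-arm QALYs encode; the one-time lump
  shrinks the difference roughly sevenfold.
* **Discounting** (`discount_method`): the 5 %-per-year rate converts to a
  monthly rate as `1.05^(1/12) − 1` (default, preserves the annual rate
  exactly) or as `0.05/12`. The difference is below 0.12 % of any output.
* **Cost attribution** (fixed, documented rather than switchable): drug,
  tests, outpatient and adverse-event costs accrue while stable (treatment
  continues until progression); the progressive-state cost subsumes
  subsequent treatment and monitoring; societal costs accrue in every alive
  state.

The base-case dominance verdict is invariant to every combination of these
switches — only the magnitudes move — which the test suite checks
exhaustively.

## Parameters

All parameters of the bundled reference set, with units:

```{r}
parameter_table(mrcc_reference())
```

Transition probabilities are per one-month cycle; utilities are annual
quality weights in [0, 1] (stable 0.730, progressive 0.660, both arms — the
trial reported no quality-of-life difference); costs are per-cycle 2022 USD
(exchange rate 6.3017 CNY/USD). The willingness-to-pay threshold,
$34,340.50 per QALY, is three times per-capita GDP, the conventional
threshold in this setting.

## Sensitivity analyses

**One-way (tornado).** Each parameter moves to its published low and high
bound (±20 % of base where no explicit range exists; the discount rate
spans 0–8 % per year) while everything else stays at base. Because the base
case sits in the dominant quadrant, the ICER is a treacherous tornado
metric: as ΔQALY passes through zero the ratio diverges and flips sign, and
several probability parameters cross that singularity inside their ranges.
The default metric is therefore incremental **NMB** at the configured
threshold, which is continuous everywhere; the ICER at each bound is always
reported alongside. One consequence worth knowing: the two
post-progression mortality probabilities produce the two widest NMB bars
and are nearly tied (within ~4 % of each other), so which arm's bar ranks
first is sensitive to conventions; the discount rate and testing costs sit
far down the ranking, with essentially no influence.

Bounds that would breach a type invariant (utility above 1, negative cost)
are clamped with a warning. The published utility ranges legitimately let
the progressive-state utility exceed the stable-state utility at opposite
bounds, so the base-case ordering check `u_prog ≤ u_stable` is relaxed
inside sensitivity runs.

**Probabilistic.** Every probability and utility gets a beta distribution,
every cost a gamma distribution, fitted by the method of moments: the mean
is the base-case value and the sd treats the (low, high) range as a central
95 % interval, `sd = (high − low)/3.92`. Parameters are sampled
independently (no correlation structure is published). Draws whose sampled
stable-state exit probabilities sum above 1 are rejected and redrawn, which
preserves the stated marginals; utility draws that cross the base-case
ordering are kept, since the utilities are shared between arms and cancel
from the increments. The discount rate is varied deterministically only.
The acceptability curve reports, per threshold λ, the fraction of draws
with `λ·ΔQALY − ΔC > 0`; with the reference parameter set it is flat near 1
across the whole grid, i.e. anlotinib is cost-effective in essentially
every draw.

## The synthetic trial generator

`simulate_trial()` produces patient-level two-arm data with exactly the
structure the model assumes: exponential PFS with rate `ln 2 / median_pfs`,
an independent exponential post-progression interval with rate
`ln 2 / (median_os − median_pfs)`, OS as their sum, and Bernoulli grade ≥ 3
adverse events. Default arm sizes are 90 and 43, the enrolment of the
underlying trial. Generator and model are mutually consistent by
construction, so the pipeline `simulate_trial() → estimate_summary() →
derive_transitions() → run_base_case()` closes end-to-end and recovers the
generating parameters as n grows.

What the generator deliberately does **not** emulate: censoring (an
administrative-cutoff hook exists but defaults off, and the summary
estimator uses plain sample medians, not Kaplan–Meier), non-exponential
hazards, correlation between toxicity and survival, and recruitment or
dropout dynamics. Passing pipeline-closure tests therefore shows the
software is internally consistent under the model's own assumptions — it
says nothing about how real mRCC data deviate from constant hazards.

## Numerical choices and degenerate inputs

* Transition probabilities are carried at full precision internally;
  rounding to 3 decimals happens only when validating against published
  values.
* ICERs are computed from full-precision aggregates, never from rounded
  ones, and are `NA` exactly when the effect difference is zero.
* A zero-width parameter range yields a degenerate distribution that
  returns the mean exactly, so an all-degenerate PSA reproduces the base
  case in every draw.
* Cohort traces conserve probability mass to 1e−12 per row; the dead
  fraction is non-decreasing by construction.
* The per-LY ICER divides by a fourth-decimal life-year difference
  (≈ 0.002 LY between these arms), so its magnitude is numerically fragile;
  treat its sign, not its size, as meaningful.

## Verification strategy and problem sizes

The test suite validates the cohort engine against two independent routes:
closed-form geometric-series results for the two-state reduction, and an
individual-level microsimulation oracle (100,000 patients stepped through
the same chain with per-patient closed-form discounted sums) that must
agree with the cohort aggregates within three Monte Carlo standard errors.
Synthetic-trial parameter recovery is tested at 100,000 patients per arm
(medians within 1 %, derived probabilities within 0.005) and at the
trial-realistic 90/43 across 500 replicates. The probabilistic analysis is
exercised at its reference size of 1000 draws; smaller draw counts are used
in structural unit tests where only determinism or shape is at stake.

## Known limitations

* Exactly two strategies are compared; there is no multi-strategy
  efficiency frontier.
* No tunnel states or time-varying transition probabilities: hazards are
  constant by design, which is what the median-based derivation encodes.
* Utilities and costs enter as fixed per-state values; no age- or
  time-dependence.
* The expected value of perfect information is not computed.
* All monetary values are fixed 2022 USD; no currency or inflation
  machinery.
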