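---
title: "Ranking long-term care facilities by potentially avoidable hospitalisations: methods"
author: "pahrank authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ranking long-term care facilities by potentially avoidable hospitalisations: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pahrank)
options(pahrank.verbose = FALSE)
```

## The problem

Residents of long-term care (LTC) facilities are hospitalised acutely far
more often than community-dwelling older people, and a sizeable share of
those admissions — pneumonia, urinary tract infection, congestive heart
failure, dehydration, falls — are regarded as *potentially avoidable*
(PAH): amenable to prevention or to management within the facility. Trials
of in-facility interventions, outreach programmes and auditors all face the
same selection question: which facilities actually have high PAH use?

The answer depends on how "high use" is measured. A facility full of frail,
high-needs residents may have a high raw admission rate that is entirely
expected; a facility with low-needs residents and a mid-table rate may be
the real outlier. This package implements a family of selection methods
spanning that spectrum, together with everything needed to run them on
linked facility/resident/discharge tables — or on synthetic data generated
with known truth.

## PAH classification

A discharge event carries an ordered list of diagnosis codes. An event is
classified PAH when **any of the first three** codes starts with a prefix
from the condition code list; a match at the fourth position or deeper never
counts. Matching is case-insensitive and dot-insensitive, so prefix `J18`
covers `J18.0`–`J18.9`.

Prefix matching (rather than exact code enumeration) was chosen so a short,
readable list reproduces condition-level intent; any study with an exact
enumerated definition can supply it through the same CSV format, one row per
prefix. The bundled default list maps each condition of a typical PAH
definition (COPD, bronchitis, pneumonia, congestive heart failure,
dehydration, urinary tract infection, anaemia, cellulitis, leg ulcers,
collapse/syncope, constipation, influenza, fall-related fractures and
injuries) to ICD-10 chapter prefixes chosen by the package authors and
annotated in the file itself. It is a documented stand-in for whatever
definition a given study uses, not an authority.

Event membership in the follow-up window uses the half-open convention
`[start, end)` on the admission date — the standard epidemiological choice,
which prevents double counting across consecutive windows. By default only
acute admissions are counted.

## Person-time

Each resident contributes exposure from `max(entry, window start)` to
`min(death, exit, window end)`, floored at zero, in years of 365.25 days
(the year length is a documented constant; day-precision dates are the
native granularity of admission and death records). An optional `exit_date`
column censors residents who leave the facility alive; without it a resident
is assumed present until death or window end, which matches data sources
that track deaths but not discharges.

When individual follow-up is unavailable — e.g. when only current resident
headcounts are known — facility person-time can be approximated as
`sum over care levels of headcount x mean survival`, where mean survival per
care level is estimated from a reference cohort as the mean of *censored*
person-time over the window. Two choices deserve note:

* the mean is computed censored at the window end rather than extrapolated,
  because the estimate feeds a denominator bounded by the window; and
* when applied, each level's mean is capped at the window length, so no
  resident can contribute more exposure than the window holds. The cap is
  our documented choice; it only binds when mean survival exceeds follow-up.

## The risk model

Resident-level PAH counts are clustered within facilities and overdispersed.
The model is a negative-binomial (NB2) mixed model with a facility random
intercept:

$$y_{ij} \sim \mathrm{NB2}(\mu_{ij}, k), \qquad
  \log \mu_{ij} = x_{ij}'\beta + \log t_{ij} + b_i, \qquad
  b_i \sim N(0, \sigma_b^2),$$

with $t_{ij}$ the resident's person-time, $k$ the NB2 size parameter
(variance $\mu + \mu^2/k$; $k \to \infty$ recovers the Poisson) and $b_i$
the facility intercept. Parameters that matter:

* `offset_mode` (default `"log_person_time"`): rates are the ranking
  currency, so person-time enters as a log offset; `"none"` models raw
  counts. Units with zero exposure cannot contribute under an offset and are
  dropped with a warning.
* `quadrature_points` (default 15): the marginal likelihood integrates each
  facility's likelihood over $b_i$ by *adaptive* Gauss–Hermite quadrature —
  nodes centred at the facility's conditional mode (found by damped Newton
  iteration on an analytic gradient/curvature) and scaled by the curvature
  there. One node is the Laplace approximation. Fifteen nodes reproduce a
  10,001-point brute-force trapezoid integration to better than $10^{-6}$
  relative error on test cohorts, at a tiny fraction of the cost.
* Optimisation is quasi-Newton (`nlminb`) over $(\beta, \log\sigma_b,
  \log k)$, 500 iterations maximum; $\sigma_b$ and/or $k$ can be fixed
  (`fix_sigma_b = 0` gives an independent NB regression, `fix_k = 1e8` is
  numerically Poisson). Standard errors come from the inverse observed
  information (numerical Hessian at the optimum); Wald p-values are
  two-sided normal. A singular information matrix (e.g. a constant
  covariate) yields missing standard errors with a warning rather than an
  error.
* The NB2 parameterisation and the $\sigma_b = 0$ collapse are exact special
  cases, both covered by tests.

The model supports two units of analysis: per-resident rows with a facility
random intercept (the default, used for variable selection), and
per-facility rows, where the "random intercept" acts as extra-NB
overdispersion. The reproduction path is: fit per-resident, then apply the
coefficients to facility-level covariate *proportions* for prediction — the
expected count for a facility is $\hat{y}_i = T_i \exp(\bar{x}_i'\hat\beta)$
at $b = 0$, with $T_i$ the facility person-years. Prediction at the
conditional mode of a *new* facility ($b = 0$) rather than marginalised over
$b$ is a deliberate simplification: ranking is monotone in either.

### Backward elimination

Covariate selection removes, at each step, the covariate with the largest
Wald p-value (ties broken by the smaller absolute standardised effect — the
effect "closer to zero") and refits, until every retained covariate has
$p \le \alpha$ (default 0.05). The intercept is never removed, candidates
are processed from a sorted list so the retained set does not depend on
input order, and the trace of removals is recorded. With calibrated
p-values each pure-noise candidate still has an ~$\alpha$ chance of
surviving in the final model — an irreducible property of
significance-threshold selection worth remembering when interpreting
retained sets.

## The ranking methods

All methods rank ascending: rank 1 is the *lowest* PAH use, rank $n$ the
highest.

| Method | Value | Interpretation |
|---|---|---|
| 1 | events / residents (or / beds) | simplest; ignores survival and turnover |
| 2 | events / person-years | the observed incidence rate |
| 3 | model-predicted expected count | case-mix-driven risk score |
| 4 | rank(2) − rank(3) | use in excess of what case-mix predicts |
| residual | observed − predicted (or Pearson) | same idea on the count scale |

Design choices that the source data leave open, fixed here and exposed as
options:

* **Method 1's denominator** — residents by default, beds available
  (`denominator = "beds"`), since either is defensible as the "simple"
  comparator and neither is canonical.
* **Method 4's sign** — the change is `rank2 − rank3`, so *positive* means
  observed above expectation; facilities are ranked by the signed change by
  default, with absolute change behind `method4_absolute`.
* **Ties** — every method's ranks must form a strict permutation of
  `1..n` (a league table of $n$ bars needs a total order, and determinism is
  essential for testing), so ties break by facility id after a stable sort.
  Values are compared at 12 significant digits first, so rates that are
  mathematically equal but computed through different denominators tie
  rather than ordering on floating-point noise.
* **Zero denominators** — a facility with no residents or no person-time is
  flagged and excluded from that method's ranking (its rank is `NA`), but
  kept in reports; silently dropping it would corrupt the permutation
  invariant.

Selection (`select_top`) takes the top `n` overall or within strata —
the regional-stratification design (e.g. 12 facilities per district health
board) is the motivating case. `compare_methods` reports top-$n$ overlap,
Spearman correlation and per-facility shifts.

## The synthetic cohort generator

The generator emulates exactly the structure the model assumes: facility
intercepts drawn $N(0, \sigma_b^2)$; independent Bernoulli resident
covariates; exponential survival by care level censored at the window end;
NB2 event counts with mean `person_time x exp(beta0 + beta'x + b_i)`;
admission dates uniform within each resident's exposure; and diagnosis codes
drawn so an exact fraction of events match the bundled code list (the rest
use a disjoint `Z99`-style space). One master seed spawns separate streams
per table, so changing resident settings does not perturb facility draws.

The `opal_like` preset emulates a census-type regional survey: 149
facilities averaging 42 residents (~6300 residents), a 22-month window, and
a baseline calibrated analytically so the marginal PAH rate is 0.34 events
per person-year — the scale of a realistic LTC cohort. The four bundled
covariates carry effects of 0.8, 0.5, 0.4 and 0.3 on the log scale at
prevalences 0.10–0.20, $\sigma_b = 0.3$, $k = 2$; no published effect sizes
exist for these predictors, so these are documented defaults chosen to be
plausible for strong clinical risk markers, not estimates. Survival rates
(0.35–0.55 deaths per person-year by care level) reflect typical LTC
mortality ordering (low < psychogeriatric < dementia < high-level care).
The `tiny` preset (5 facilities × ~10 residents) runs the full pipeline in
seconds for oracle tests.

What the generator does *not* emulate: real covariate correlation
structures, seasonal admission patterns, facility turnover, coding error, or
informative drop-out. Passing tests therefore demonstrate that the methods
are implemented correctly and behave as the theory predicts under the
model's own assumptions — not that the model is adequate for any particular
real cohort.

## Numerical choices and degenerate inputs

* Year length 365.25 days; dates are day-precision ISO-8601.
* Adaptive quadrature: Newton mode search to $10^{-10}$ step tolerance,
  with steps clamped at ±2 for stability; log-sum-exp for the node
  combination; the NB2 log-mass uses `log1p(mu/k)` so $k = 10^8$ is stable.
* Optimiser bounds: $\sigma_b \in [10^{-6}, 50]$, $k \in [10^{-4},
  10^{10}]$ on the log scale; a fit at the lower $\sigma_b$ bound is an
  effectively-zero random effect.
* Problem sizes in the test suite were chosen to exercise the survey scale
  where it matters (parameter recovery and elimination run 20 replicates at
  149 × 42) and small oracle instances everywhere else.
* Degenerate inputs are first-class: empty event files, facilities with
  zero residents, constant covariates, all-candidates-eliminated models and
  zero-exposure residents each have a defined, warned behaviour described on
  the respective help pages.

## Known limitations

* Wald-based elimination inherits the usual caveats of stepwise selection:
  noise survives with probability ~α per candidate, and p-values of the
  retained model are not selection-adjusted.
* The approximate person-time denominator assumes the reference cohort's
  care-level survival transfers to the current headcounts.
* Prediction at $b = 0$ ignores shrinkage of observed facility effects;
  methods that need calibrated per-facility posteriors (e.g. funnel plots
  or Bayesian profiling) are out of scope.
* No uncertainty is attached to ranks; a league table's ordering near the
  middle is highly unstable, which is precisely why several methods are
  offered and compared.
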