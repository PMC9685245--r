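---
title: "Weighted multistate estimation of return-to-work effects"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted multistate estimation of return-to-work effects}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rtwmstate)
```

## The model and its estimands

`rtwmstate` analyses work-life trajectories after entry into long-term
full-time sickness absence as a six-state process: full-time sickness absence
(`FSA`), graded sickness absence (`GSA`), work, non-employment, education,
and absorbing death. All transitions between transient states are allowed and
death competes from every state. The causal estimands are, per state and per
day over 500 days of follow-up,

* the counterfactual marginal state probability $\pi^a(t)$ — the probability
  of occupying the state at day $t$ had everyone's baseline exposure been
  fixed at $a \in \{0, 1\}$;
* their difference $\theta(t) = \pi^1(t) - \pi^0(t)$; and
* the expected length of stay (ELOS) over the first year,
  $\int_0^{365} \pi^a_s(t)\,dt$ per state $s$, and its between-arm
  difference.

Identification rests on the usual trio of assumptions: no unmeasured
confounding given the baseline covariates, positivity, and consistency, plus
right-censoring that is independent of the state history given those
covariates. Confounding adjustment uses baseline stabilised
inverse-probability-of-treatment weights from a main-effects logistic
propensity model. Within each arm the transition hazards are estimated with
weighted Nelson–Aalen estimators and composed into state occupation
probabilities with the Aalen–Johansen product-integral. The state occupation
probability is consistently estimated by this plug-in even when the process
is not Markov, so Markovianity is documented here as a convenience of the
*generator*, not an assumption of the *estimator*.

## From raw records to counting processes

Registry records overlap: an employer keeps a worker on its payroll record
while a sickness-absence spell runs. `resolve_records()` assigns each
calendar day the single highest-precedence record type covering it —
sickness absence first, then work, then education — with grade 100 mapping to
`FSA` and lower grades to `GSA`. Uncovered days are non-employment when later
records exist; a trailing uncovered period is loss to follow-up and becomes
the person's right-censoring day. Overlapping sickness-absence records with
contradictory grades are rejected outright rather than silently resolved.

Time is integer days and every interval is half-open `[start, end)`:
precedence, merging, and tied events are then unambiguous, and transitions
need strictly positive sojourns (zero-length fragments produced by overlap
resolution are dropped).

Cohort entry (`extract_baseline_cohort()`) takes each person's first
full-time episode that (1) lasts at least `min_sa_days` (default 17 days,
i.e. strictly more than 16 calendar days counted from the first day),
(2) starts inside the inclusion window, and (3) has no sickness absence in
the `washout_days` (default 365) before its first day. Requiring all three of
the *same* episode keeps inclusion monotone in `min_sa_days`. The treatment
of a sickness-absence episode that starts before the washout window but
reaches into it is genuinely underdetermined; `strict_washout = TRUE`
(default) excludes such candidates, `FALSE` ignores episodes that merely
overlap the boundary. Exposure at baseline is read off the employer(s) whose
work records cover the baseline day — a person concurrently employed by
several companies is exposed if *any* of them holds the agreement — falling
back to the covariate table's employer.

Death is not a registry record type; it enters through a `death_day` column
in the covariate table, emulating mortality-register linkage. A death after
the person's last record is treated as occurring after censoring (the states
in between are unobservable), so it does not extend follow-up.

## Numerical choices in the estimator

* The risk set for an event at day $s$ contains episodes with
  `entry < s <= exit`; a person censored exactly at $s$ is still at risk.
* Ties (several transitions on one day) are handled jointly in a single
  matrix factor $(I + d\hat A(s))$ per day, with diagonal increments equal to
  minus the row sums — the standard correct treatment at registry day
  resolution, and the reason every factor is row-stochastic by construction.
  Hand-built increments whose row sums exceed one are rejected.
* Curves are right-continuous step functions evaluated on the integer-day
  grid `0:horizon`; ELOS is the exact step-function integral
  $\sum_k \pi(t_k)(t_{k+1}-t_k)$ clipped at `tau` (default 365; curves run to
  `horizon` 500). Per arm the state-wise ELOS sums to `tau` up to floating
  error, which the tests assert at $10^{-9}$.
* On a two-state graph the estimator collapses exactly (to machine precision)
  to one minus Kaplan–Meier, which the tests verify against an independent
  survival-package fit.
* Censoring is handled purely by risk-set removal; no censoring weights are
  used. This is valid under censoring independent of the state history given
  baseline covariates, and is stated here as an assumption.
* Weights default to *no truncation*; symmetric quantile truncation is
  available as an explicit option and logs the applied bounds. Reference
  levels for indicator coding follow the factor level order (first level =
  reference); character input is coded alphabetically, so supply factors to
  control the reference. Missing confounder values are rejected, never
  imputed.

## Inference

`cluster_bootstrap()` resamples whole companies with replacement because the
exposure is assigned at company level; individuals travel with their company
and duplicated companies count as fresh clusters. Every replicate re-fits the
propensity model and recomputes weights, curves, effects and ELOS — freezing
the weights would ignore their estimation uncertainty, and a test asserts
that freezing measurably changes band widths on a confounded cohort.
Percentile intervals are the default (the method-compatible choice when
nothing further is specified); normal-approximation bands are available as an
option. Replicate $r$ draws from a stream derived deterministically from
`(seed, r)`, so results are independent of execution order, and replicates
with an empty arm are redrawn with a logged count.

## What the synthetic generator emulates — and what it does not

`simulate_cohort()` generates the study conditions the package is tested
under:

* **Companies as clusters.** Company covariates (size class, industry,
  region) are drawn first; the exposure is a company-level Bernoulli draw
  from a logistic model on those covariates; included persons
  (`1 + Poisson(3)` per company) inherit them. The company-size *category* is
  a confounder label, deliberately independent of the number of included
  persons so that the oracle's person-level stratum distribution stays exact.
* **Confounded intensities.** Post-baseline trajectories follow a
  continuous-time Markov chain with per-day intensities
  $q_{hj}(a, l) = Q^0_{hj} \exp(\beta_{hj} a + \delta_{hj}(l))$. The
  confounders that shift the intensities (sex, company size, industry) are
  the same ones that drive assignment, with signs aligned so the crude
  between-arm contrast in work probability is materially biased (about
  4–6 percentage points against the exposed arm at its peak, computable
  exactly with `true_unweighted_contrast()`); this is the test bed the
  weighting must clean up. Scenarios: `"beneficial"` (effect plus
  confounding), `"confounded_null"` ($\beta = 0$, confounding intact) and
  `"null"` (randomised exposure).
* **Qualifying entry without selection.** Inclusion requires an initial FSA
  episode of ≥ 17 days. The generator produces a deterministic 17-day stub
  followed by a fresh chain from FSA — by memorylessness exactly the law of
  the chain conditioned on inclusion — so the oracle stays exact: $\pi^a(t)$
  is a point mass on FSA before day 17 and
  $\sum_l P(L=l)\, e_{FSA}' \exp(Q(a,l)(t-17))$ afterwards, a finite mixture
  of matrix exponentials over the (small, fully categorical) confounder
  strata. Event times are drawn by competing exponentials and rounded *up* to
  whole days; evaluated at integer days this rounding is exact for occupation
  probabilities (a transition at time $u$ is applied at day $t$ iff
  $u \le t$), it only compresses multiple same-day transitions.
* **Registry artefacts.** Emitted work records span whole employment runs,
  deliberately overlapping the sickness-absence records inside them, and the
  last pre-baseline work record runs into the qualifying episode — so every
  simulated cohort exercises the resolver's precedence rules. Independent
  exponential right-censoring (default rate `4e-4`/day) truncates records;
  deaths appear only in the mortality-register column. Trajectories are
  simulated `margin_days` (default 200) beyond the horizon so that
  non-employment spells inside the horizon usually have later records, as in
  a registry extracted after the administrative censoring date.
* **Pre-baseline negative controls.** A three-state chain (work,
  non-employment, education) over the 730 days before baseline depends on
  the confounders only — never on the exposure — and contains no sickness
  absence, so the washout holds by construction and the weighted pre-baseline
  between-arm difference is exactly zero in truth while the crude one is not
  (`true_prebaseline_contrast()`).

Default baseline intensities were chosen once so that roughly half to
three-quarters of a cohort is back in work within 100 days and most remaining
full-time absence has resolved within a year, a qualitatively realistic
return-to-work profile; these defaults are documentation, not calibration to
any real cohort. What the generator does **not** emulate: duration-dependent
(semi-Markov) intensities, real calendar effects, benefit-type distinctions
within sickness absence (only the grade matters for state assignment),
informative censoring, or the magnitudes of any particular country's
registries — so passing tests demonstrate correctness of the machinery under
a faithful but idealised data-generating process, not real-world effect
sizes.

## Problem sizes and residual Monte-Carlo error

The simulation-based checks use cohorts of about 20,000 persons in 5,000
companies for estimator recovery and null safety, 10,000 persons for
generator/oracle consistency, and 200 replicate cohorts of about 2,000
persons (bootstrap `B = 200`, follow-up to day 100) for the coverage study of
the company-clustered percentile band — sizes at which each check completes
in minutes on one CPU while leaving the Monte-Carlo noise well below the
effects being checked, with one caveat the test suite reports honestly: at
20,000 persons the *supremum* over all 501 grid days of
$|\hat\theta_{WORK}(t) - \theta_{WORK}(t)|$ has expectation around 0.017, so
a 0.015 sup-norm tolerance is met only for favourable seeds even though the
estimator is unbiased; the pointwise error is far smaller.

## Subgroups and sensitivity analyses

`run_full_analysis()` accepts subgroup filters (sex, diagnosis group of the
qualifying episode, industry subsets, and exclusion of pregnancy-related
diagnoses). Weights are re-fitted *within* the subgroup by default — matching
per-subgroup estimation — with reuse of the full-cohort weights available as
a flag; constant confounders (such as sex inside a single-sex subgroup) are
dropped from the refit with a message. `run_adjustment_sweep()` re-runs the
estimation over a list of adjustment sets to show how omitted confounders
bias the answer, and `negative_control()` reuses the main-analysis weights —
bitwise, never refit — on the pre-baseline window, reporting per-state
maximum absolute between-arm differences as a diagnostic (no p-value is
attached; the check is deliberately qualitative).

## Known limitations

* The propensity model uses main effects only; interactions must be encoded
  by the caller (e.g. via a combined factor).
* Gaps between a person's last record and a registered death are treated as
  censoring at the last record, losing any unobservable non-employment time
  before death; with realistic mortality this is negligible but it is a
  convention, not a theorem.
* The ELOS integral is day-resolution quadrature of a step function; against
  a continuous-time truth this differs by up to half a day per state near
  steep probability changes.
* Analytic (martingale) variance estimators are out of scope; inference is
  bootstrap-only.
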