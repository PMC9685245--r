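# rtwmstate

Causal multistate analysis of return to work after long-term sickness
absence, with inverse-probability-of-treatment (IPT) weighting and
company-clustered bootstrap inference.

## The problem

Administrative registries record a worker's life as dated, overlapping
records: certified sickness-absence spells (full-time or graded), employment
relationships, and enrolment in education. After someone enters a first
long-term full-time sickness absence (more than 16 calendar days, counted
from the first day), the question is whether a **company-level baseline
exposure** — here, a workplace agreement giving access to measures that
prevent and reduce sickness absence — changes how they subsequently move
between six states:

```
FSA  full-time sickness absence     NONEMP  non-employment
GSA  graded sickness absence        EDU     education
WORK work                           DEATH   absorbing
```

Individuals move back and forth between the five transient states; death
competes from every state. Because the exposure is chosen by companies, not
randomised, the comparison must be adjusted for baseline confounders
(sex, age group, calendar year of inclusion, education level, industry,
company size, region).

## The estimator

For exposure arm *a*, the package estimates marginal state occupation
probabilities with a weighted multistate estimator:

1. **Propensity model.** Logistic regression of the exposure *A* on the
   confounders *L*; stabilised IPT weights
   `w_i = P(A=1) / P(A=1 | L_i)` for the exposed and
   `w_i = P(A=0) / P(A=0 | L_i)` for the unexposed.
2. **Weighted Nelson–Aalen.** For every transition *h → j*, the cumulative
   hazard increment at event day *s* is
   `dÂ_hj(s) = Σ_i w_i ΔN_i,hj(s) / Σ_i w_i Y_i,h(s)`, computed separately
   within each arm (the group-wise equivalent of a weighted additive-hazards
   fit adjusting only for the exposure).
3. **Aalen–Johansen.** State probabilities are the product-integral
   `π^a(t) = p_0' Π_{s≤t} (I + dÂ(s))` with `p_0` a point mass on FSA.
4. **Effect curves and ELOS.** The average treatment effect is
   `θ(t) = π¹(t) − π⁰(t)` per state and day; the expected length of stay
   (ELOS) over the first year is the area under each state's probability
   curve on `[0, 365]`.
5. **Inference.** 95% percentile bands from a clustered bootstrap that
   resamples whole companies and re-fits the propensity model inside every
   replicate.

Because the real registry data are not publicly available, the package ships
a synthetic registry generator (`simulate_cohort()`) with company-clustered
confounded exposure assignment, overlapping raw records, recurrent six-state
trajectories and an **exact matrix-exponential oracle**
(`true_state_probabilities()`) for the counterfactual curves, plus a
negative-outcome-control diagnostic on pre-baseline histories.

## Worked example

```r
library(rtwmstate)

cfg <- sim_config(scenario = "beneficial", n_companies = 500, seed = 2026)
sim <- simulate_cohort(cfg)
sim
#> Synthetic registry cohort: 2035 persons in 500 companies (scenario beneficial, seed 2026)
#>   8522 raw records; exposure prevalence 0.478

records  <- dplyr::bind_rows(sim$records, simulate_prebaseline(sim))
episodes <- resolve_records(records)                  # precedence: SA > work > education
cohort   <- extract_baseline_cohort(episodes, sim$covariates,
                                    records = records, companies = sim$companies)
trajectories <- clock_reset_and_truncate(episodes, cohort, horizon = 500,
                                         death = sim$covariates)
transitions  <- to_counting_process(trajectories)

adj <- c("sex", "age_group", "education", "inclusion_year",
         "industry", "company_size", "region")
weights <- stabilized_weights(fit_propensity(cohort, adj))
curves  <- estimate_arm_curves(transitions, cohort, weights)
effect  <- effect_curve(curves)

tidy(effect) |> dplyr::filter(state == "WORK") |> dplyr::slice_max(estimate)
#>    time state estimate
#> 1   101 WORK     0.113
```

The exposed arm's probability of being in work peaks 11.3 percentage points
above the unexposed arm's at day 101 in this small synthetic cohort (the
generator's built-in effect is strong; its exact value is available from
`true_effect_curve(sim$truth)`).

```r
elos(curves, tau = 365)
#> # A tibble: 6 × 4
#>   state  elos_0 elos_1    diff
#> 1 FSA     77.4   62.6  -14.8
#> 2 GSA      8.15   7.36  -0.792
#> 3 WORK   236.   254.    18.4
#> 4 NONEMP  30.8   27.4   -3.43
#> 5 EDU      9.73   8.65  -1.08
#> 6 DEATH    2.82   4.52   1.70
```

Over the first year, exposed workers spend on average 18.4 more days in work
and 14.8 fewer days in full-time sickness absence. Per arm the six ELOS
values sum to exactly 365 days.

```r
boot <- cluster_bootstrap(cohort, transitions, adj, B = 200, seed = 2027)
boot
#> Company-clustered bootstrap: B = 200 (percentile 95% bands, 0 redraws)
#>   peak WORK effect 0.1135 at day 101 (0.0694, 0.1619)
```

Plots: `autoplot(curves)` (stacked state probabilities), `autoplot(boot)`
(effect curves with bands), `sequence_plot(trajectories, cohort,
group_var = "industry")` (individual histories), and
`autoplot(balance_table(cohort, weights))` (covariate balance).
The whole pipeline, including subgroup filters, the negative control and a
run manifest, is also available as one call:
`run_full_analysis(list(simulate = list(scenario = "beneficial",
n_companies = 500), seed = 1, outdir = "results"))` — or driven by a YAML
config file.

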