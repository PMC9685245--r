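library(dplyr)

# Shared fixtures. Large simulation runs used by several acceptance tests are
# built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

ADJ_FULL <- c("sex", "age_group", "education", "inclusion_year", "industry",
              "company_size", "region")

# full records-based pipeline on a simulated cohort; returns the pieces the
# tests need
run_records_pipeline <- function(scenario, n_companies, seed,
                                 with_prebaseline = TRUE, horizon = 500) {
  cfg <- sim_config(scenario = scenario, n_companies = n_companies, seed = seed)
  sim <- simulate_cohort(cfg)
  records <- if (with_prebaseline) {
    dplyr::bind_rows(sim$records, simulate_prebaseline(sim))
  } else {
    sim$records
  }
  episodes <- resolve_records(records)
  cohort <- extract_baseline_cohort(
    episodes, sim$covariates, records = records, companies = sim$companies,
    inclusion_window = c(cfg$inclusion_start,
                         cfg$inclusion_start + cfg$inclusion_span_days))
  trajectories <- clock_reset_and_truncate(episodes, cohort, horizon = horizon,
                                           death = sim$covariates)
  transitions <- to_counting_process(trajectories)
  weights <- stabilized_weights(fit_propensity(cohort, ADJ_FULL))
  curves_w <- estimate_arm_curves(transitions, cohort, weights, horizon = horizon)
  curves_u <- estimate_arm_curves(transitions, cohort, NULL, horizon = horizon)
  pre_traj <- episodes %>%
    dplyr::inner_join(dplyr::select(cohort, person_id, baseline_day),
                      by = "person_id") %>%
    dplyr::mutate(start_t = start_day - baseline_day,
                  end_t = pmin(end_day - baseline_day, 0)) %>%
    dplyr::filter(start_t < 0, end_t > start_t) %>%
    dplyr::select(person_id, state, start_t, end_t)
  list(sim = sim, episodes = episodes, cohort = cohort,
       trajectories = trajectories, transitions = transitions,
       weights = weights, curves_w = curves_w, curves_u = curves_u,
       effect_w = effect_curve(curves_w), effect_u = effect_curve(curves_u),
       pre_traj = pre_traj, truth = sim$truth)
}

# large confounded-null run shared by the null-safety and negative-control
# acceptance tests (about 20,000 persons)
acc_confounded_null <- function() {
  if (is.null(.fixture_cache$cn)) {
    .fixture_cache$cn <- run_records_pipeline("confounded_null",
                                              n_companies = 5000, seed = 1)
  }
  .fixture_cache$cn
}

# small beneficial run shared by cheap unit tests
small_run <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- run_records_pipeline("beneficial",
                                                 n_companies = 150, seed = 42)
  }
  .fixture_cache$small
}

sup_state_error <- function(effect, oracle, state) {
  e <- tidy(effect); o <- tidy(oracle)
  max(abs(e$estimate[e$state == state] - o$estimate[o$state == state]))
}
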