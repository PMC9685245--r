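# Baseline cohort extraction, clock reset, counting-process conversion.

ep <- function(person, state, start, end) {
  tibble::tibble(person_id = person, state = state, start_day = start,
                 end_day = end)
}

covs <- function(ids, exposure = 1) {
  tibble::tibble(person_id = ids, exposure = exposure, sex = "female")
}

test_that("a 17-day FSA episode qualifies, a 16-day one does not", {
  hist17 <- dplyr::bind_rows(ep(1, "WORK", 0, 400), ep(1, "FSA", 400, 417),
                             ep(1, "WORK", 417, 500))
  hist16 <- dplyr::bind_rows(ep(2, "WORK", 0, 400), ep(2, "FSA", 400, 416),
                             ep(2, "WORK", 416, 500))
  coh <- extract_baseline_cohort(dplyr::bind_rows(hist17, hist16), covs(1:2))
  expect_equal(coh$person_id, 1)
  expect_equal(coh$baseline_day, 400)
})

test_that("sickness absence in the washout window excludes the episode", {
  # GSA episode 100 days before the candidate baseline
  h <- dplyr::bind_rows(ep(1, "WORK", 0, 250), ep(1, "GSA", 250, 260),
                        ep(1, "WORK", 260, 400), ep(1, "FSA", 400, 430))
  expect_equal(nrow(extract_baseline_cohort(h, covs(1))), 0L)
  # same history but washout shortened below the gap
  coh <- extract_baseline_cohort(h, covs(1), washout_days = 100)
  expect_equal(coh$baseline_day, 400)
})

test_that("strict and lenient washout differ for boundary-spanning episodes", {
  # SA starts before the washout window but extends into it
  h <- dplyr::bind_rows(ep(1, "FSA", 0, 60), ep(1, "WORK", 60, 400),
                        ep(1, "FSA", 400, 430))
  strict <- extract_baseline_cohort(h, covs(1), washout_days = 365,
                                    inclusion_window = c(300, 500))
  lenient <- extract_baseline_cohort(h, covs(1), washout_days = 365,
                                     inclusion_window = c(300, 500),
                                     strict_washout = FALSE)
  expect_equal(nrow(strict), 0L)
  expect_equal(lenient$baseline_day, 400)
})

test_that("empty histories give an empty cohort and missing covariates error", {
  expect_equal(nrow(extract_baseline_cohort(ep(1, "FSA", 0, 30)[0, ],
                                            covs(integer(0)))), 0L)
  expect_error(extract_baseline_cohort(ep(1, "FSA", 0, 30), covs(2)),
               "missing covariate rows")
})

test_that("raising min_sa_days never adds persons (monotone inclusion)", {
  withr::with_seed(7, {
    records <- random_records(200, span = 600)
  })
  episodes <- resolve_records(records)
  cv <- covs(unique(records$person_id))
  included <- lapply(c(5, 10, 17, 25), function(m) {
    extract_baseline_cohort(episodes, cv, min_sa_days = m)$person_id
  })
  for (i in 2:4) {
    expect_true(all(included[[i]] %in% included[[i - 1]]))
  }
})

test_that("exposure uses any concurrent employer holding the agreement", {
  h <- dplyr::bind_rows(ep(1, "WORK", 0, 400), ep(1, "FSA", 400, 430))
  recs <- tibble::tibble(
    person_id = 1, record_type = "work",
    start_day = c(0, 300), end_day = c(410, 430),
    grade = NA_real_, company_id = c(10L, 20L))
  companies <- tibble::tibble(company_id = c(10L, 20L), ia = c(0, 1))
  cv <- tibble::tibble(person_id = 1, company_id = 10L, sex = "female")
  coh <- extract_baseline_cohort(h, cv, records = recs, companies = companies)
  expect_equal(coh$exposure, 1)  # second employer has the agreement
  # without the second employer, falls back to the covariate-table company
  coh0 <- extract_baseline_cohort(h, cv, records = recs[1, ],
                                  companies = companies)
  expect_equal(coh0$exposure, 0)
})

test_that("clock reset shifts, truncates at the horizon and handles death", {
  h <- dplyr::bind_rows(ep(1, "FSA", 100, 130), ep(1, "WORK", 130, 420),
                        ep(2, "FSA", 100, 150), ep(2, "WORK", 150, 900),
                        ep(3, "FSA", 100, 300))
  base <- tibble::tibble(person_id = 1:3, baseline_day = 100)
  death <- tibble::tibble(person_id = 1:3,
                          death_day = c(NA, NA, 300))
  traj <- clock_reset_and_truncate(h, base, horizon = 500, death = death)
  # censored before the horizon
  t1 <- traj[traj$person_id == 1, ]
  expect_equal(max(t1$end_t), 320)
  # administratively truncated at the horizon
  t2 <- traj[traj$person_id == 2, ]
  expect_equal(max(t2$end_t), 500)
  # death within observed follow-up becomes an absorbing episode to the horizon
  t3 <- traj[traj$person_id == 3, ]
  expect_equal(tail(t3$state, 1), "DEATH")
  expect_equal(t3$start_t[t3$state == "DEATH"], 200)
  expect_equal(max(t3$end_t), 500)
  # death after censoring is ignored
  traj2 <- clock_reset_and_truncate(
    h[1:2, ], base[1, ], horizon = 500,
    death = tibble::tibble(person_id = 1, death_day = 450))
  expect_false("DEATH" %in% traj2$state)
})

test_that("clock reset rejects histories that do not start in FSA", {
  h <- ep(1, "WORK", 100, 200)
  expect_error(clock_reset_and_truncate(
    h, tibble::tibble(person_id = 1, baseline_day = 100)),
    "not FSA")
})

test_that("counting-process records follow episodes and conserve person-time", {
  traj <- tibble::tibble(
    person_id = c(1, 1, 2, 2, 2, 3),
    state = c("FSA", "WORK", "FSA", "WORK", "DEATH", "FSA"),
    start_t = c(0, 30, 0, 20, 60, 0),
    end_t = c(30, 500, 20, 60, 500, 500))
  tr <- to_counting_process(traj)
  expect_equal(tr$to_state[tr$person_id == 1], c("WORK", "CENSORED"))
  expect_equal(tr$to_state[tr$person_id == 2], c("WORK", "DEATH"))
  # one record per transient episode
  expect_equal(nrow(tr), sum(traj$state != "DEATH"))
  # person-time conservation over transient episodes
  expect_equal(sum(tr$exit_t - tr$entry_t),
               sum((traj$end_t - traj$start_t)[traj$state != "DEATH"]))
  expect_true(all(tr$exit_t > tr$entry_t))
  expect_true(all(tr$from_state != "DEATH"))
})
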