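# Weighted Nelson-Aalen, Aalen-Johansen, effect curves, expected length of
# stay.

tr_row <- function(person, from, entry, exit, to) {
  tibble::tibble(person_id = person, from_state = from, entry_t = entry,
                 exit_t = exit, to_state = to)
}

test_that("Nelson-Aalen increments: classical, weighted, and empty cases", {
  # 10 at risk, 2 events on the same day: increment 2/10
  tr <- dplyr::bind_rows(
    tr_row(1:2, "FSA", 0, 20, "WORK"),
    tr_row(3:10, "FSA", 0, 100, "CENSORED"))
  na <- weighted_nelson_aalen(tr, "FSA", "WORK")
  expect_equal(na$time, 20)
  expect_equal(na$increment, 0.2)
  # weights {2,1,1,1}, event by the weight-2 person: increment 2/5
  tr2 <- dplyr::bind_rows(tr_row(1, "FSA", 0, 10, "WORK"),
                          tr_row(2:4, "FSA", 0, 50, "CENSORED"))
  w <- tibble::tibble(person_id = 1:4, weight = c(2, 1, 1, 1))
  na2 <- weighted_nelson_aalen(tr2, "FSA", "WORK", weights = w)
  expect_equal(na2$increment, 2 / 5)
  expect_equal(na2$n_risk, 5)
  # no events: identically zero cumulative hazard
  na3 <- weighted_nelson_aalen(tr2, "FSA", "EDU", weights = w)
  expect_equal(nrow(na3), 0L)
})

test_that("risk sets respect late entry and include persons censored at the event day", {
  tr <- dplyr::bind_rows(
    tr_row(1, "FSA", 0, 30, "WORK"),
    tr_row(2, "FSA", 10, 30, "CENSORED"),  # censored exactly at the event day
    tr_row(3, "FSA", 35, 60, "CENSORED"))  # enters after the event
  na <- weighted_nelson_aalen(tr, "FSA", "WORK")
  expect_equal(na$n_risk, 2)
  expect_equal(na$increment, 0.5)
})

test_that("Aalen-Johansen reduces exactly to one minus Kaplan-Meier on two states", {
  skip_if_not_installed("survival")
  withr::with_seed(5, {
    n <- 250
    time <- ceiling(rexp(n, 0.02))
    cens <- ceiling(rexp(n, 0.015))
    obs <- pmin(time, cens, 200)
    status <- as.numeric(time <= pmin(cens, 200))
  })
  tr <- tibble::tibble(person_id = seq_len(n), from_state = "FSA",
                       entry_t = 0, exit_t = obs,
                       to_state = ifelse(status == 1, "DEATH", "CENSORED"))
  na <- weighted_nelson_aalen(tr, "FSA", "DEATH")
  curve <- aalen_johansen(list(na), horizon = 200,
                          states = c("FSA", "DEATH"))
  km <- survival::survfit(survival::Surv(obs, status) ~ 1)
  km_surv <- summary(km, times = 0:200, extend = TRUE)$surv
  expect_equal(curve$DEATH, 1 - km_surv, tolerance = 1e-12)
})

test_that("Aalen-Johansen matches the hand-computed matrix product on a 3-state toy", {
  # 4 persons all start in FSA; day 2: person 1 -> WORK (4 at risk);
  # day 5: person 2 -> DEATH (3 at risk)
  tr <- dplyr::bind_rows(
    tr_row(1, "FSA", 0, 2, "WORK"), tr_row(1, "WORK", 2, 10, "CENSORED"),
    tr_row(2, "FSA", 0, 5, "DEATH"),
    tr_row(3, "FSA", 0, 10, "CENSORED"), tr_row(4, "FSA", 0, 10, "CENSORED"))
  sts <- c("FSA", "WORK", "DEATH")
  hz <- list(weighted_nelson_aalen(tr, "FSA", "WORK"),
             weighted_nelson_aalen(tr, "FSA", "DEATH"))
  curve <- aalen_johansen(hz, horizon = 10, states = sts)
  # hand product: (1,0,0) (I + dA(2)) (I + dA(5))
  # after day 2: (3/4, 1/4, 0); after day 5: (3/4 * 2/3, 1/4, 3/4 * 1/3)
  expect_equal(unlist(curve[curve$time == 1, sts]), c(FSA = 1, WORK = 0, DEATH = 0))
  expect_equal(unlist(curve[curve$time == 3, sts]),
               c(FSA = 0.75, WORK = 0.25, DEATH = 0))
  expect_equal(unlist(curve[curve$time == 10, sts]),
               c(FSA = 0.5, WORK = 0.25, DEATH = 0.25))
  expect_equal(rowSums(as.matrix(curve[sts])), rep(1, 11))
})

test_that("hand-built hazards with an invalid row are rejected", {
  bad <- tibble::tibble(from = c("FSA", "FSA"), to = c("WORK", "DEATH"),
                        time = c(3, 3), increment = c(0.7, 0.6))
  expect_error(aalen_johansen(bad, horizon = 5), "negative entry")
  neg <- tibble::tibble(from = "FSA", to = "WORK", time = 3, increment = -0.1)
  expect_error(aalen_johansen(neg, horizon = 5), "negative entry")
})

test_that("per-arm estimation: curves are proper distributions, death monotone", {
  run <- small_run()
  m <- as.matrix(run$curves_w[rtw_states()])
  expect_lt(max(abs(rowSums(m) - 1)), 1e-10)
  expect_true(all(m >= -1e-12 & m <= 1 + 1e-12))
  for (a in c(0, 1)) {
    d <- run$curves_w$DEATH[run$curves_w$arm == a]
    expect_true(all(diff(d) >= -1e-12))
  }
  expect_error(estimate_arm_curves(run$transitions,
                                   dplyr::mutate(run$cohort, exposure = 1),
                                   run$weights),
               "non-empty")
})

test_that("weighted and unweighted curves agree under randomised exposure", {
  run_rand <- run_records_pipeline("null", n_companies = 2000, seed = 77,
                                   with_prebaseline = FALSE)
  dw <- tidy(run_rand$effect_w)
  du <- tidy(run_rand$effect_u)
  expect_lt(max(abs(dw$estimate - du$estimate)), 0.015)
  # and the weighted effect is near zero (no effect, no confounding)
  expect_lt(max(abs(dw$estimate)), 0.04)
})

test_that("effect curves subtract and sum to zero across states", {
  run <- small_run()
  eff <- run$effect_w
  states <- rtw_states()
  expect_lt(max(abs(rowSums(as.matrix(eff[states])))), 1e-10)
  # identical curves give an identically zero effect
  c1 <- run$curves_w %>% dplyr::filter(arm == 1)
  zero <- effect_curve(c1, c1)
  expect_equal(max(abs(as.matrix(zero[states]))), 0)
  # plain subtraction on a chosen day
  c0 <- run$curves_w %>% dplyr::filter(arm == 0)
  expect_equal(eff$WORK[eff$time == 50],
               c1$WORK[c1$time == 50] - c0$WORK[c0$time == 50])
  # grid mismatch is an error
  expect_error(effect_curve(c1[1:10, ], c0), "common time grid")
})

test_that("expected length of stay integrates step curves exactly", {
  states <- rtw_states()
  # pi_WORK = 1 on the whole year
  flat <- tibble::as_tibble(matrix(0, 501, 6, dimnames = list(NULL, states)))
  flat$WORK <- 1
  curve <- dplyr::bind_cols(tibble::tibble(arm = 1, time = 0:500), flat)
  attr(curve, "states") <- states
  e1 <- elos(curve, tau = 365)
  expect_equal(e1$elos[e1$state == "WORK"], 365)
  # single step: pi_FSA = 1 on [0, 100), 0 after (moves to WORK)
  step <- tibble::as_tibble(matrix(0, 501, 6, dimnames = list(NULL, states)))
  step$FSA <- as.numeric(0:500 < 100)
  step$WORK <- 1 - step$FSA
  curve2 <- dplyr::bind_cols(tibble::tibble(arm = 1, time = 0:500), step)
  attr(curve2, "states") <- states
  e2 <- elos(curve2, tau = 365)
  expect_equal(e2$elos[e2$state == "FSA"], 100)
  expect_equal(e2$elos[e2$state == "WORK"], 265)
  # conservation on estimated curves, and tau > horizon rejected
  run <- small_run()
  el <- elos(run$curves_w, tau = 365)
  expect_equal(sum(el$elos_1), 365, tolerance = 1e-9)
  expect_equal(sum(el$elos_0), 365, tolerance = 1e-9)
  expect_error(elos(run$curves_w, tau = 600), "exceeds")
})
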