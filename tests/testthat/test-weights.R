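# Propensity fitting, stabilised weights, balance.

two_strata_cohort <- function() {
  # stratum x: P(A=1|x) = 0.8; stratum y: 0.2; marginal 0.5
  tibble::tibble(
    person_id = 1:20,
    exposure = c(rep(1, 8), rep(0, 2), rep(1, 2), rep(0, 8)),
    stratum = c(rep("x", 10), rep("y", 10)))
}

test_that("intercept-only model gives prevalence scores and unit weights", {
  coh <- two_strata_cohort()
  ps <- fit_propensity(coh, character())
  expect_equal(ps$scores$pscore, rep(0.5, 20))
  w <- stabilized_weights(ps)
  expect_equal(w$weight, rep(1, 20))
})

test_that("a saturated model recovers within-stratum frequencies and the two-stratum closed form", {
  coh <- two_strata_cohort()
  ps <- fit_propensity(coh, "stratum")
  expect_equal(ps$scores$pscore, rep(c(0.8, 0.2), each = 10),
               tolerance = 1e-9)
  w <- stabilized_weights(ps)
  # closed form: exposed in the 0.8-stratum get 0.5 / 0.8 = 0.625
  expect_equal(w$weight[1], 0.625, tolerance = 1e-12)
  expect_equal(w$weight[11], 0.5 / 0.2, tolerance = 1e-9)
  expect_equal(w$weight[9], 0.5 / 0.2, tolerance = 1e-9)  # unexposed in x
  # within-arm mean weight is exactly 1 under a saturated model
  expect_equal(mean(w$weight[w$exposure == 1]), 1, tolerance = 1e-12)
  expect_equal(mean(w$weight[w$exposure == 0]), 1, tolerance = 1e-12)
})

test_that("coefficients of the assignment model are recovered on simulation", {
  sim <- simulate_cohort(sim_config(scenario = "confounded_null",
                                    n_companies = 5000, seed = 51))
  coh <- rtwmstate:::.sim_cohort(sim)
  coh$company_size <- factor(coh$company_size,
                             levels = c("small", "medium", "large"))
  coh$industry <- factor(coh$industry,
                         levels = c("manufacturing", "health", "services"))
  coh$region <- factor(coh$region, levels = c("east", "west", "north"))
  ps <- fit_propensity(coh, c("company_size", "industry", "region"))
  est <- tidy(ps)
  g <- sim$truth$gamma
  truth <- c(`(Intercept)` = g[["intercept"]],
             company_sizemedium = g[["size_medium"]],
             company_sizelarge = g[["size_large"]],
             industryhealth = g[["industry_health"]],
             industryservices = g[["industry_services"]],
             regionwest = g[["region_west"]],
             regionnorth = g[["region_north"]])
  for (nm in names(truth)) {
    row <- est[est$term == nm, ]
    # clustered assignment: persons share their company's draw, so the
    # effective sample size is the company count; allow 3 SE on that scale
    se_cluster <- row$std.error * sqrt(nrow(coh) / nrow(sim$companies))
    expect_lt(abs(row$estimate - truth[[nm]]), 3 * se_cluster)
  }
})

test_that("separation and positivity problems are reported as errors", {
  coh <- tibble::tibble(person_id = 1:20,
                        exposure = rep(c(1, 0), each = 10),
                        z = rep(c("a", "b"), each = 10))
  expect_error(fit_propensity(coh, "z"), "separation|positivity")
  expect_error(stabilized_weights(c(0.5, 1), exposure = c(0, 1)), "positivity")
  expect_error(fit_propensity(coh[c(1, 11:20), ], character()),
               "at least 2 persons")
})

test_that("missing confounder values are rejected", {
  coh <- two_strata_cohort()
  coh$stratum[3] <- NA
  expect_error(fit_propensity(coh, "stratum"), "missing confounder")
})

test_that("balance table: unit weights reproduce unweighted columns and shares sum to 1", {
  run <- small_run()
  coh <- run$cohort
  unit <- stabilized_weights(rep(0.5, nrow(coh)), exposure = coh$exposure,
                             person_id = coh$person_id)
  bt <- balance_table(coh, unit, confounders = c("sex", "company_size"))
  expect_equal(bt$p_exposed_weighted, bt$p_exposed, tolerance = 1e-12)
  expect_equal(bt$p_unexposed_weighted, bt$p_unexposed, tolerance = 1e-12)
  expect_equal(bt$smd_weighted, bt$smd_unweighted, tolerance = 1e-12)
  bt2 <- balance_table(coh, run$weights)
  sums <- bt2 %>%
    dplyr::group_by(confounder) %>%
    dplyr::summarise(s1 = sum(p_exposed_weighted),
                     s0 = sum(p_unexposed_weighted))
  expect_equal(sums$s1, rep(1, nrow(sums)), tolerance = 1e-9)
  expect_equal(sums$s0, rep(1, nrow(sums)), tolerance = 1e-9)
})

test_that("weighting improves covariate balance in a confounded cohort", {
  run <- small_run()
  bt <- balance_table(run$cohort, run$weights,
                      confounders = c("company_size", "industry", "region"))
  expect_lt(max(abs(bt$smd_weighted)), max(abs(bt$smd_unweighted)))
})

test_that("weight truncation caps the extremes and is logged", {
  run <- small_run()
  ps <- fit_propensity(run$cohort, ADJ_FULL)
  expect_message(wt <- stabilized_weights(ps, truncation_quantile = 0.05),
                 "truncated")
  w0 <- stabilized_weights(ps)
  expect_lt(max(wt$weight), max(w0$weight))
  expect_equal(sort(unique(round(wt$weight[wt$weight >= max(wt$weight)], 10))),
               round(max(wt$weight), 10))
})
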