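# Synthetic registry generator.
#
# Post-baseline trajectories are a continuous-time Markov chain on the six
# states with per-day intensities q_hj(a, l) = Q0_hj * exp(beta_hj * a +
# delta_hj(l)), started in full-time sickness absence. Inclusion requires a
# qualifying FSA episode of at least `qualifying_sa_days` days; by
# memorylessness this is generated as a deterministic stub of that length
# followed by a fresh chain from FSA, which is exactly the law of the chain
# conditioned on inclusion. The exposure is assigned at company level by a
# logistic model on company covariates, which also shift the transition
# intensities through the individuals -- the confounding path the IPT weights
# must remove.

.SIM_LEVELS <- list(
  company_size = c("small", "medium", "large"),
  industry = c("manufacturing", "health", "services"),
  region = c("east", "west", "north"),
  sex = c("female", "male"),
  age_group = c("28-32", "33-37", "38-43"),
  education = c("lower_secondary", "upper_secondary", "college", "university"),
  diagnosis_group = c("musculoskeletal", "psychological", "pregnancy_related",
                      "other")
)

.SIM_PROBS <- list(
  company_size = c(0.45, 0.35, 0.20),
  industry = c(0.35, 0.30, 0.35),
  region = c(0.50, 0.30, 0.20),
  female_by_industry = c(manufacturing = 0.30, health = 0.75, services = 0.50),
  age_group = c(0.28, 0.50, 0.22),
  education = c(0.30, 0.41, 0.24, 0.05),
  diagnosis_female = c(0.30, 0.18, 0.16, 0.36),
  diagnosis_male = c(0.36, 0.19, 0.00, 0.45)
)

#' Configuration for the synthetic registry generator
#'
#' Bundles the study-design parameters of the generator. The defaults are the
#' package's reference study conditions: 500 companies of mean size 4 included
#' persons (about 2,000 persons), 500 days of follow-up, a 17-day qualifying
#' episode, a 730-day pre-baseline history and a light independent
#' right-censoring rate.
#'
#' @param scenario `"beneficial"` (confounded exposure with a positive
#'   return-to-work effect), `"confounded_null"` (confounded exposure, zero
#'   effect) or `"null"` (randomised exposure, zero effect).
#' @param n_companies Number of companies (clusters).
#' @param seed Integer seed; mandatory, the generator is fully deterministic
#'   given the config.
#' @param persons_per_company_mean Included persons per company are
#'   `1 + Poisson(persons_per_company_mean)`.
#' @param horizon_days Follow-up horizon in days.
#' @param margin_days Extra simulated days beyond the horizon so that
#'   non-employment periods inside the horizon usually have later records.
#' @param qualifying_sa_days Minimum length (days) of the initial full-time
#'   sickness-absence episode; the generated baseline episodes always satisfy
#'   it.
#' @param pre_days Length of the simulated pre-baseline history (days).
#' @param inclusion_start,inclusion_span_days Calendar window (half-open, in
#'   days) from which baseline days are drawn uniformly.
#' @param censor_rate Per-day rate of independent exponential right-censoring
#'   (loss to follow-up).
#' @param graded_grade Grade recorded on graded sickness-absence records.
#' @return A list of class `rtw_sim_config`.
#' @export
sim_config <- function(scenario = c("beneficial", "confounded_null", "null"),
                       n_companies = 500, seed,
                       persons_per_company_mean = 3,
                       horizon_days = 500, margin_days = 200,
                       qualifying_sa_days = 17,
                       pre_days = 730,
                       inclusion_start = 1095, inclusion_span_days = 7 * 365,
                       censor_rate = 4e-4,
                       graded_grade = 50) {
  scenario <- match.arg(scenario)
  if (missing(seed) || !.is_scalar_number(seed)) {
    abort("`seed` is mandatory and must be a single integer")
  }
  stopifnot(n_companies >= 2, horizon_days >= 1, qualifying_sa_days >= 1,
            pre_days >= 0, censor_rate >= 0,
            graded_grade > 0, graded_grade < 100,
            inclusion_start >= pre_days)
  structure(list(
    scenario = scenario, n_companies = n_companies, seed = as.integer(seed),
    persons_per_company_mean = persons_per_company_mean,
    horizon_days = horizon_days, margin_days = margin_days,
    qualifying_sa_days = qualifying_sa_days, pre_days = pre_days,
    inclusion_start = inclusion_start,
    inclusion_span_days = inclusion_span_days,
    censor_rate = censor_rate, graded_grade = graded_grade
  ), class = "rtw_sim_config")
}

# baseline per-day intensities; rows sum to 0, DEATH row identically 0
.sim_Q0 <- function() {
  s <- .RTW_STATES
  Q <- matrix(0, 6, 6, dimnames = list(s, s))
  Q["FSA", c("GSA", "WORK", "NONEMP", "EDU", "DEATH")] <-
    c(0.004, 0.025, 0.003, 0.0005, 1e-4)
  Q["GSA", c("FSA", "WORK", "NONEMP", "EDU", "DEATH")] <-
    c(0.010, 0.030, 0.002, 0.0005, 1e-4)
  Q["WORK", c("FSA", "GSA", "NONEMP", "EDU", "DEATH")] <-
    c(0.0015, 0.0005, 0.001, 0.0003, 5e-5)
  Q["NONEMP", c("FSA", "GSA", "WORK", "EDU", "DEATH")] <-
    c(0.002, 0.0005, 0.010, 0.001, 1e-4)
  Q["EDU", c("FSA", "GSA", "WORK", "NONEMP", "DEATH")] <-
    c(0.001, 0.0005, 0.008, 0.003, 5e-5)
  diag(Q) <- -rowSums(Q)
  Q
}

.sim_Q0_pre <- function() {
  s <- c("WORK", "NONEMP", "EDU")
  Q <- matrix(0, 3, 3, dimnames = list(s, s))
  Q["WORK", c("NONEMP", "EDU")] <- c(0.0015, 0.0003)
  Q["NONEMP", c("WORK", "EDU")] <- c(0.008, 0.001)
  Q["EDU", c("WORK", "NONEMP")] <- c(0.006, 0.002)
  diag(Q) <- -rowSums(Q)
  Q
}

# exposure log rate multipliers (beneficial scenario)
.sim_beta <- function(scenario) {
  B <- matrix(0, 6, 6, dimnames = list(.RTW_STATES, .RTW_STATES))
  if (scenario == "beneficial") {
    B["FSA", "WORK"] <- 0.25
    B["FSA", "GSA"] <- 0.30
    B["GSA", "WORK"] <- 0.20
    B["WORK", "FSA"] <- -0.10
    B["NONEMP", "WORK"] <- 0.10
  }
  B
}

# confounder log rate multipliers per rate stratum (sex x size x industry).
# High-exposure strata (large companies, health industry, women) have slower
# return to work, so crude contrasts are biased against the exposed arm.
.sim_delta <- function(strata, states, pre = FALSE) {
  n <- nrow(strata)
  D <- array(0, c(length(states), length(states), n),
             dimnames = list(states, states, NULL))
  med <- strata$company_size == "medium"
  lrg <- strata$company_size == "large"
  hea <- strata$industry == "health"
  fem <- strata$sex == "female"
  if (!pre) {
    D["FSA", "WORK", ] <- -0.20 * med - 0.40 * lrg - 0.35 * hea - 0.15 * fem
    D["WORK", "FSA", ] <- 0.20 * lrg + 0.15 * hea
    D["FSA", "NONEMP", ] <- 0.25 * lrg
    D["NONEMP", "WORK", ] <- -0.30 * lrg - 0.20 * hea
  } else {
    D["WORK", "NONEMP", ] <- 0.25 * med + 0.60 * lrg + 0.40 * hea
    D["NONEMP", "WORK", ] <- -0.20 * med - 0.45 * lrg - 0.30 * hea
  }
  D
}

.sim_gamma <- function(scenario) {
  if (scenario == "null") {
    return(c(intercept = -0.2, size_medium = 0, size_large = 0,
             industry_health = 0, industry_services = 0,
             region_west = 0, region_north = 0))
  }
  c(intercept = -0.9, size_medium = 0.8, size_large = 1.6,
    industry_health = 1.0, industry_services = 0.2,
    region_west = 0.2, region_north = -0.2)
}

.company_logit <- function(gamma, company_size, industry, region) {
  gamma[["intercept"]] +
    gamma[["size_medium"]] * (company_size == "medium") +
    gamma[["size_large"]] * (company_size == "large") +
    gamma[["industry_health"]] * (industry == "health") +
    gamma[["industry_services"]] * (industry == "services") +
    gamma[["region_west"]] * (region == "west") +
    gamma[["region_north"]] * (region == "north")
}

#' Ground truth of a simulation scenario
#'
#' Assembles the exact data-generating parameters of a scenario: the baseline
#' intensity matrix, exposure and confounder log rate multipliers, the
#' company-level assignment coefficients and the exact finite distribution of
#' the confounder strata, together with the pre-baseline chain. These feed the
#' matrix-exponential oracle [true_state_probabilities()].
#'
#' @param config An [sim_config()].
#' @return An object of class `rtw_truth`.
#' @export
simulation_truth <- function(config) {
  rate_strata <- tidyr::expand_grid(
    sex = .SIM_LEVELS$sex,
    company_size = .SIM_LEVELS$company_size,
    industry = .SIM_LEVELS$industry) %>%
    mutate(rate_stratum = dplyr::row_number())
  strata <- tidyr::expand_grid(
    company_size = .SIM_LEVELS$company_size,
    industry = .SIM_LEVELS$industry,
    region = .SIM_LEVELS$region,
    sex = .SIM_LEVELS$sex) %>%
    mutate(
      prob = .SIM_PROBS$company_size[match(.data$company_size,
                                           .SIM_LEVELS$company_size)] *
        .SIM_PROBS$industry[match(.data$industry, .SIM_LEVELS$industry)] *
        .SIM_PROBS$region[match(.data$region, .SIM_LEVELS$region)] *
        ifelse(.data$sex == "female",
               .SIM_PROBS$female_by_industry[.data$industry],
               1 - .SIM_PROBS$female_by_industry[.data$industry]))
  gamma <- .sim_gamma(config$scenario)
  strata$pa <- plogis(.company_logit(gamma, strata$company_size,
                                     strata$industry, strata$region))
  strata <- strata %>%
    left_join(rate_strata, by = c("sex", "company_size", "industry"))
  structure(list(
    states = .RTW_STATES,
    Q0 = .sim_Q0(),
    beta = .sim_beta(config$scenario),
    rate_strata = rate_strata,
    delta = .sim_delta(rate_strata, .RTW_STATES, pre = FALSE),
    gamma = gamma,
    strata = strata,
    pre = list(states = c("WORK", "NONEMP", "EDU"),
               Q0 = .sim_Q0_pre(),
               delta = .sim_delta(rate_strata, c("WORK", "NONEMP", "EDU"),
                                  pre = TRUE)),
    qualifying_sa_days = config$qualifying_sa_days,
    pre_days = config$pre_days,
    horizon = config$horizon_days,
    scenario = config$scenario
  ), class = "rtw_truth")
}

# intensity matrix for one arm and rate stratum (off-diagonals scaled, diagonal
# recomputed); validates conservativeness
.truth_Q <- function(truth, arm, rate_stratum, pre = FALSE) {
  if (pre) {
    Q0 <- truth$pre$Q0
    logm <- truth$pre$delta[, , rate_stratum]
  } else {
    Q0 <- truth$Q0
    logm <- truth$beta * arm + truth$delta[, , rate_stratum]
  }
  Q <- Q0 * exp(logm)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

.validate_intensity <- function(Q) {
  off <- Q; diag(off) <- 0
  if (any(off < 0) || any(abs(rowSums(Q)) > 1e-10)) {
    abort("non-conservative intensity matrix: off-diagonals must be >= 0 and rows sum to 0")
  }
  invisible(Q)
}

# first row of expm(Q * t) for a set of non-negative times; exact via repeated
# one-day steps when all times are integers, expm(Q * dt) steps otherwise
.expm_first_row <- function(Q, times, p0 = NULL) {
  .validate_intensity(Q)
  ns <- nrow(Q)
  if (is.null(p0)) p0 <- c(1, rep(0, ns - 1L))
  ut <- sort(unique(times))
  out <- matrix(NA_real_, length(ut), ns)
  if (isTRUE(all(ut == round(ut)))) {
    M <- as.matrix(Matrix::expm(Q))
    v <- p0
    k <- 0
    for (i in seq_along(ut)) {
      while (k < ut[i]) { v <- v %*% M; k <- k + 1 }
      out[i, ] <- v
    }
  } else {
    v <- p0
    prev <- 0
    for (i in seq_along(ut)) {
      dt <- ut[i] - prev
      if (dt > 0) v <- v %*% as.matrix(Matrix::expm(Q * dt))
      out[i, ] <- v
      prev <- ut[i]
    }
  }
  out[match(times, ut), , drop = FALSE]
}

#' Exact marginal state probabilities under a fixed exposure
#'
#' The oracle for the counterfactual marginal state probabilities
#' \eqn{\pi^a(t)}: an exact mixture of matrix exponentials over the finite
#' confounder distribution,
#' \eqn{\pi^a(t) = \sum_l P(L = l)\, e_{FSA}' \exp(Q(a, l) t)}. The generated
#' cohorts condition on a qualifying initial episode of
#' `truth$qualifying_sa_days` days, which by memorylessness shifts the chain's
#' clock: with the default `delay`, the curve is a point mass on `FSA` before
#' the delay and the mixture evaluated at `t - delay` afterwards. Use
#' `delay = 0` for the plain unconditional chain.
#'
#' @param truth An `rtw_truth` from [simulation_truth()], or a list with a
#'   single intensity matrix `Q0` (then the mixture is over one stratum).
#' @param arm Exposure arm, 0 or 1.
#' @param times Numeric vector of evaluation times (days).
#' @param delay Initial deterministic sojourn in `FSA` (days).
#' @return An `rtw_curves` tibble (`arm`, `time`, one column per state).
#' @export
true_state_probabilities <- function(truth, arm, times = 0:truth$horizon,
                                     delay = truth$qualifying_sa_days) {
  stopifnot(arm %in% c(0, 1), all(times >= 0))
  probs <- truth$strata %>%
    group_by(.data$rate_stratum) %>%
    summarise(prob = sum(.data$prob), .groups = "drop")
  shifted <- pmax(times - delay, 0)
  acc <- matrix(0, length(times), length(truth$states))
  for (i in seq_len(nrow(probs))) {
    Q <- .truth_Q(truth, arm, probs$rate_stratum[i])
    acc <- acc + probs$prob[i] * .expm_first_row(Q, shifted)
  }
  if (delay > 0) {
    pre_mask <- times < delay
    acc[pre_mask, ] <- matrix(rep(c(1, rep(0, length(truth$states) - 1L)),
                                  sum(pre_mask)), ncol = length(truth$states),
                              byrow = TRUE)
  }
  colnames(acc) <- truth$states
  out <- bind_cols(tibble::tibble(arm = arm, time = times),
                   tibble::as_tibble(acc))
  .new_rtw_tbl(out, "rtw_curves", states = truth$states,
               horizon = max(times), p0 = c(1, rep(0, length(truth$states) - 1L)))
}

#' Exact effect curve of a scenario
#'
#' \eqn{\theta(t) = \pi^1(t) - \pi^0(t)} computed from the matrix-exponential
#' oracle.
#'
#' @inheritParams true_state_probabilities
#' @return An `rtw_effect` tibble.
#' @export
true_effect_curve <- function(truth, times = 0:truth$horizon,
                              delay = truth$qualifying_sa_days) {
  effect_curve(true_state_probabilities(truth, 1, times, delay),
               true_state_probabilities(truth, 0, times, delay))
}

# stratum distribution within an exposure arm: P(rate stratum | A = a)
.arm_stratum_probs <- function(truth, arm) {
  truth$strata %>%
    mutate(w = .data$prob * (if (arm == 1) .data$pa else 1 - .data$pa)) %>%
    group_by(.data$rate_stratum) %>%
    summarise(w = sum(.data$w), .groups = "drop") %>%
    mutate(w = .data$w / sum(.data$w))
}

#' Exact crude (unweighted) contrast implied by a scenario
#'
#' The large-sample limit of the unweighted between-arm difference in state
#' probabilities: each arm's curve is the mixture of stratum curves under that
#' arm's confounder distribution \eqn{P(L = l \mid A = a)}. In confounded
#' scenarios with zero exposure effect this is the pure confounding bias.
#'
#' @inheritParams true_state_probabilities
#' @return An `rtw_effect` tibble.
#' @export
true_unweighted_contrast <- function(truth, times = 0:truth$horizon,
                                     delay = truth$qualifying_sa_days) {
  curve_for <- function(arm) {
    pw <- .arm_stratum_probs(truth, arm)
    shifted <- pmax(times - delay, 0)
    acc <- matrix(0, length(times), length(truth$states))
    for (i in seq_len(nrow(pw))) {
      Q <- .truth_Q(truth, arm, pw$rate_stratum[i])
      acc <- acc + pw$w[i] * .expm_first_row(Q, shifted)
    }
    if (delay > 0) {
      pre_mask <- times < delay
      acc[pre_mask, ] <- matrix(rep(c(1, rep(0, 5)), sum(pre_mask)),
                                ncol = 6, byrow = TRUE)
    }
    colnames(acc) <- truth$states
    out <- bind_cols(tibble::tibble(arm = arm, time = times),
                     tibble::as_tibble(acc))
    .new_rtw_tbl(out, "rtw_curves", states = truth$states)
  }
  effect_curve(curve_for(1), curve_for(0))
}

#' Exact pre-baseline arm contrast implied by a scenario
#'
#' Pre-baseline trajectories depend on the confounders only, never on the
#' exposure, so after correct weighting the between-arm difference is exactly
#' zero. The crude (unweighted) difference is the mixture difference induced
#' by the arm-specific confounder distributions; this function computes it
#' exactly for the three pre-baseline states.
#'
#' @param truth An `rtw_truth`.
#' @param times Days since the start of the pre-baseline window (the chain
#'   starts in `WORK` at time 0).
#' @return A tibble with `time` and one difference column per pre-baseline
#'   state.
#' @export
true_prebaseline_contrast <- function(truth, times = seq(0, truth$pre_days, by = 10)) {
  states <- truth$pre$states
  curve_for <- function(arm) {
    pw <- .arm_stratum_probs(truth, arm)
    acc <- matrix(0, length(times), length(states))
    for (i in seq_len(nrow(pw))) {
      Q <- .truth_Q(truth, arm, pw$rate_stratum[i], pre = TRUE)
      acc <- acc + pw$w[i] * .expm_first_row(Q, times)
    }
    acc
  }
  d <- curve_for(1) - curve_for(0)
  colnames(d) <- states
  out <- bind_cols(tibble::tibble(time = times), tibble::as_tibble(d))
  .new_rtw_tbl(out, "rtw_effect", states = states)
}

#' Exact expected length of stay of a scenario
#'
#' Day-grid quadrature of the oracle state probability curves (matching the
#' estimator's step-function integral) over `[0, tau]`, per arm, with the
#' between-arm difference.
#'
#' @inheritParams true_state_probabilities
#' @param tau Integration horizon in days.
#' @return An `rtw_elos` tibble with `state`, `elos_1`, `elos_0`, `diff`.
#' @export
true_elos <- function(truth, tau = 365, delay = truth$qualifying_sa_days) {
  c1 <- true_state_probabilities(truth, 1, 0:tau, delay)
  c0 <- true_state_probabilities(truth, 0, 0:tau, delay)
  elos(bind_rows(c1, c0) %>%
         .new_rtw_tbl("rtw_curves", states = truth$states), tau = tau)
}

# ---- trajectory simulation -------------------------------------------------

# vectorised competing-exponentials simulation of a CTMC for many persons.
# group: per-person index into the stacked rate matrix Qflat ((G*ns) x ns,
# off-diagonal rates, zero diagonal); start/clock in continuous days.
# Returns continuous episodes ordered by person then time.
.sim_ctmc <- function(group, Qflat, n_states, start_state, t0, t_end) {
  n <- length(group)
  cur <- rep.int(start_state, n)
  ep_start <- rep(0, n)
  clock <- rep(t0, length.out = n)
  act <- which(t_end > 0)
  UT <- upper.tri(diag(n_states), diag = TRUE) * 1
  res_p <- res_s <- res_a <- res_b <- list(); k <- 0L
  while (length(act)) {
    rows <- (group[act] - 1L) * n_states + cur[act]
    R <- Qflat[rows, , drop = FALSE]
    tot <- rowSums(R)
    soj <- rep(Inf, length(act))
    pos <- tot > 0
    if (any(pos)) soj[pos] <- rexp(sum(pos), tot[pos])
    t_new <- clock[act] + soj
    done <- t_new >= t_end[act]
    k <- k + 1L
    res_p[[k]] <- act
    res_s[[k]] <- cur[act]
    res_a[[k]] <- ep_start[act]
    res_b[[k]] <- pmin(t_new, t_end[act])
    nd <- which(!done)
    if (length(nd)) {
      i <- act[nd]
      cumr <- R[nd, , drop = FALSE] %*% UT
      u <- runif(length(i)) * tot[nd]
      nxt <- rowSums(cumr < u) + 1L
      cur[i] <- nxt
      ep_start[i] <- t_new[nd]
      clock[i] <- t_new[nd]
    }
    act <- act[nd]
  }
  person <- unlist(res_p, use.names = FALSE)
  o <- order(person, unlist(res_a, use.names = FALSE))
  list(person = person[o],
       state = unlist(res_s, use.names = FALSE)[o],
       start = unlist(res_a, use.names = FALSE)[o],
       end = unlist(res_b, use.names = FALSE)[o])
}

# round continuous episodes to whole-day episodes: event times are rounded up,
# zero-length day fragments dropped, adjacent equal states merged
.episodes_to_days <- function(ep, states) {
  end_day <- ceiling(ep$end)
  person <- ep$person
  first <- c(TRUE, person[-1] != person[-length(person)])
  start_day <- c(0, end_day[-length(end_day)])
  start_day[first] <- floor(ep$start[first])
  keep <- end_day > start_day
  df <- tibble::tibble(person = person[keep],
                       state = states[ep$state[keep]],
                       start_t = start_day[keep], end_t = end_day[keep])
  if (nrow(df) < 2L) return(df)
  new_run <- df$person != lag(df$person, default = df$person[1] - 1L) |
    df$state != lag(df$state, default = "")
  run <- cumsum(new_run)
  out <- df[!duplicated(run), ]
  out$end_t <- df$end_t[c(which(new_run)[-1] - 1L, nrow(df))]
  out
}

# stacked per-(arm x rate-stratum) rate matrix for the simulator
.stacked_rates <- function(truth, pre = FALSE) {
  ns <- if (pre) 3L else 6L
  n_rs <- nrow(truth$rate_strata)
  G <- if (pre) n_rs else 2L * n_rs
  Qflat <- matrix(0, G * ns, ns)
  for (g in seq_len(G)) {
    arm <- if (pre) 0 else (g - 1L) %/% n_rs
    rs <- if (pre) g else ((g - 1L) %% n_rs) + 1L
    Q <- .truth_Q(truth, arm, rs, pre = pre)
    diag(Q) <- 0
    Qflat[(g - 1L) * ns + seq_len(ns), ] <- Q
  }
  Qflat
}

#' Simulate a registry-like cohort with known ground truth
#'
#' Draws companies with covariates, assigns the company-level exposure by the
#' scenario's logistic model, populates companies with individuals inheriting
#' the company covariates, and simulates each individual's post-baseline
#' trajectory from the scenario's continuous-time Markov chain (started in
#' full-time sickness absence, with a qualifying initial episode of at least
#' `qualifying_sa_days` days, independent right-censoring, and death as an
#' absorbing competing state). Raw records are emitted with deliberate
#' overlaps: employer work records span sickness-absence periods, so the
#' record resolver's precedence rules are exercised on every cohort.
#'
#' @param config An [sim_config()].
#' @return An object of class `rtw_sim`: a list with `records` (raw registry
#'   records), `covariates` (one row per person, including `death_day` from
#'   the mortality register), `companies` (`company_id`, `ia`, covariates),
#'   `persons` (generator-internal person table incl. baseline day and rate
#'   stratum), `trajectories` (the true post-baseline day-level trajectories,
#'   relative to baseline) and `truth` ([simulation_truth()]).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "rtw_sim_config"))
  truth <- simulation_truth(config)
  withr::with_seed(config$seed, {
    nc <- config$n_companies
    companies <- tibble::tibble(
      company_id = seq_len(nc),
      company_size = sample(.SIM_LEVELS$company_size, nc, TRUE,
                            .SIM_PROBS$company_size),
      industry = sample(.SIM_LEVELS$industry, nc, TRUE, .SIM_PROBS$industry),
      region = sample(.SIM_LEVELS$region, nc, TRUE, .SIM_PROBS$region))
    companies$ia <- rbinom(nc, 1, plogis(.company_logit(
      truth$gamma, companies$company_size, companies$industry,
      companies$region)))

    n_per <- 1L + rpois(nc, config$persons_per_company_mean)
    persons <- companies[rep.int(seq_len(nc), n_per), ] %>%
      mutate(person_id = dplyr::row_number())
    n <- nrow(persons)
    p_fem <- .SIM_PROBS$female_by_industry[persons$industry]
    persons$sex <- ifelse(runif(n) < p_fem, "female", "male")
    persons$age_group <- sample(.SIM_LEVELS$age_group, n, TRUE,
                                .SIM_PROBS$age_group)
    persons$education <- sample(.SIM_LEVELS$education, n, TRUE,
                                .SIM_PROBS$education)
    persons$diagnosis_group <- ifelse(
      persons$sex == "female",
      sample(.SIM_LEVELS$diagnosis_group, n, TRUE, .SIM_PROBS$diagnosis_female),
      sample(.SIM_LEVELS$diagnosis_group, n, TRUE, .SIM_PROBS$diagnosis_male))
    persons$baseline_day <- config$inclusion_start +
      sample.int(config$inclusion_span_days, n, replace = TRUE) - 1L
    persons$inclusion_year <- paste0(
      "y", (persons$baseline_day - config$inclusion_start) %/% 365 + 1L)
    persons$rate_stratum <- truth$rate_strata$rate_stratum[
      match(paste(persons$sex, persons$company_size, persons$industry),
            paste(truth$rate_strata$sex, truth$rate_strata$company_size,
                  truth$rate_strata$industry))]

    # post-baseline chain: FSA stub then fresh chain, truncated at independent
    # censoring (floored to whole days) or the administrative span
    span <- config$horizon_days + config$margin_days
    cens <- if (config$censor_rate > 0) rexp(n, config$censor_rate) else
      rep(Inf, n)
    obs_end <- floor(pmin(cens, span))
    group <- persons$rate_stratum + nrow(truth$rate_strata) * companies$ia[
      match(persons$company_id, companies$company_id)]
    Qflat <- .stacked_rates(truth)
    ep <- .sim_ctmc(group, Qflat, 6L, start_state = 1L,
                    t0 = config$qualifying_sa_days, t_end = obs_end)
    traj <- .episodes_to_days(ep, .RTW_STATES)
    traj <- tibble::tibble(person_id = persons$person_id[traj$person],
                           state = traj$state, start_t = traj$start_t,
                           end_t = traj$end_t)

    death <- traj %>%
      filter(.data$state == "DEATH") %>%
      group_by(.data$person_id) %>%
      summarise(death_rel = min(.data$start_t), .groups = "drop")
    persons$death_rel <- death$death_rel[match(persons$person_id,
                                               death$person_id)]
    persons$obs_end <- obs_end
    persons$exposure <- companies$ia[match(persons$company_id,
                                           companies$company_id)]

    records <- .emit_post_records(traj, persons, config)

    covariates <- persons %>%
      transmute(.data$person_id, .data$company_id, .data$sex, .data$age_group,
                .data$education, .data$inclusion_year, .data$industry,
                .data$company_size, .data$region, .data$diagnosis_group,
                death_day = .data$baseline_day + .data$death_rel)

    structure(list(records = records, covariates = covariates,
                   companies = companies, persons = persons,
                   trajectories = traj, truth = truth, config = config),
              class = "rtw_sim")
  })
}

# raw records from post-baseline day trajectories; employer work records span
# maximal runs of {FSA, GSA, WORK} containing at least one WORK episode
.emit_post_records <- function(traj, persons, config) {
  base <- persons$baseline_day[match(traj$person_id, persons$person_id)]
  dx <- persons$diagnosis_group[match(traj$person_id, persons$person_id)]
  comp <- persons$company_id[match(traj$person_id, persons$person_id)]

  sa <- traj$state %in% c("FSA", "GSA")
  sa_rec <- tibble::tibble(
    person_id = traj$person_id[sa], record_type = "sickness_absence",
    start_day = base[sa] + traj$start_t[sa], end_day = base[sa] + traj$end_t[sa],
    grade = ifelse(traj$state[sa] == "FSA", 100, config$graded_grade),
    diagnosis_group = dx[sa], company_id = NA_integer_)

  edu <- traj$state == "EDU"
  edu_rec <- tibble::tibble(
    person_id = traj$person_id[edu], record_type = "education",
    start_day = base[edu] + traj$start_t[edu], end_day = base[edu] + traj$end_t[edu],
    grade = NA_real_, diagnosis_group = NA_character_,
    company_id = NA_integer_)

  in_run <- traj$state %in% c("FSA", "GSA", "WORK")
  brk <- !in_run |
    traj$person_id != lag(traj$person_id, default = traj$person_id[1] - 1L) |
    traj$start_t != lag(traj$end_t, default = -1L)
  run <- cumsum(brk)
  runs <- tibble::tibble(person_id = traj$person_id, run = run,
                         state = traj$state, start_t = traj$start_t,
                         end_t = traj$end_t, base = base, comp = comp)[in_run, ] %>%
    group_by(.data$run) %>%
    summarise(person_id = .data$person_id[1],
              any_work = any(.data$state == "WORK"),
              start_day = .data$base[1] + min(.data$start_t),
              end_day = .data$base[1] + max(.data$end_t),
              company_id = .data$comp[1], .groups = "drop") %>%
    filter(.data$any_work)
  work_rec <- tibble::tibble(
    person_id = runs$person_id, record_type = "work",
    start_day = runs$start_day, end_day = runs$end_day,
    grade = NA_real_, diagnosis_group = NA_character_,
    company_id = runs$company_id)

  bind_rows(sa_rec, work_rec, edu_rec) %>%
    arrange(.data$person_id, .data$start_day, .data$record_type)
}

#' Simulate pre-baseline histories (negative-control window)
#'
#' Generates each person's pre-baseline records over the `pre_days` before
#' their baseline from a three-state chain (work, non-employment, education)
#' started in work. The pre-baseline intensities depend on the confounders
#' only -- never on the exposure -- and contain no sickness absence, so the
#' washout rule is respected by construction. The final pre-baseline work
#' record, when the person is working right before baseline, extends into the
#' qualifying sickness-absence episode, creating the registry-typical overlap
#' of an employer record with a sickness-absence record.
#'
#' @param sim An `rtw_sim` from [simulate_cohort()].
#' @return A raw records tibble in the same format as `sim$records`.
#' @export
simulate_prebaseline <- function(sim) {
  stopifnot(inherits(sim, "rtw_sim"))
  config <- sim$config
  truth <- sim$truth
  persons <- sim$persons
  if (config$pre_days <= 0) return(sim$records[0, ])
  withr::with_seed(.substream_seed(config$seed, 1L), {
    n <- nrow(persons)
    Qflat <- .stacked_rates(truth, pre = TRUE)
    ep <- .sim_ctmc(persons$rate_stratum, Qflat, 3L, start_state = 1L,
                    t0 = 0, t_end = rep(config$pre_days, n))
    traj <- .episodes_to_days(ep, truth$pre$states)
    pid <- persons$person_id[traj$person]
    base <- persons$baseline_day[traj$person]
    comp <- persons$company_id[traj$person]
    cal_start <- base - config$pre_days + traj$start_t
    cal_end <- base - config$pre_days + traj$end_t
    is_work <- traj$state == "WORK"
    # employer record continuing through the initial sickness-absence episode
    extend <- is_work & cal_end == base
    cal_end[extend] <- base[extend] + config$qualifying_sa_days
    work_rec <- tibble::tibble(
      person_id = pid[is_work], record_type = "work",
      start_day = cal_start[is_work], end_day = cal_end[is_work],
      grade = NA_real_, diagnosis_group = NA_character_,
      company_id = comp[is_work])
    is_edu <- traj$state == "EDU"
    edu_rec <- tibble::tibble(
      person_id = pid[is_edu], record_type = "education",
      start_day = cal_start[is_edu], end_day = cal_end[is_edu],
      grade = NA_real_, diagnosis_group = NA_character_,
      company_id = NA_integer_)
    bind_rows(work_rec, edu_rec) %>%
      arrange(.data$person_id, .data$start_day)
  })
}

# true post-baseline trajectories in the analysis representation: truncated at
# the horizon, death extended to the horizon (used as a resolver-free path in
# simulation studies)
.sim_trajectories <- function(sim, horizon = sim$config$horizon_days) {
  traj <- sim$trajectories %>%
    mutate(end_t = pmin(.data$end_t, horizon)) %>%
    filter(.data$start_t < horizon, .data$end_t > .data$start_t)
  traj <- traj %>%
    mutate(end_t = ifelse(.data$state == "DEATH", horizon, .data$end_t))
  .new_rtw_tbl(traj, "rtw_trajectories", horizon = horizon)
}

# cohort table straight from the generator (resolver-free path)
.sim_cohort <- function(sim) {
  cohort <- sim$persons %>%
    transmute(.data$person_id, .data$company_id, baseline_day = .data$baseline_day,
              exposure = .data$exposure, .data$sex, .data$age_group,
              .data$education, .data$inclusion_year, .data$industry,
              .data$company_size, .data$region, .data$diagnosis_group)
  .new_rtw_tbl(cohort, "rtw_cohort")
}

#' @export
print.rtw_sim <- function(x, ...) {
  cat(sprintf(
    "Synthetic registry cohort: %d persons in %d companies (scenario %s, seed %d)\n",
    nrow(x$persons), nrow(x$companies), x$config$scenario, x$config$seed))
  cat(sprintf("  %d raw records; exposure prevalence %.3f\n",
              nrow(x$records), mean(x$persons$exposure)))
  invisible(x)
}
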