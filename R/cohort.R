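#' Extract the baseline cohort from resolved histories
#'
#' Scans each person's resolved episode history for the first full-time
#' sickness-absence (`FSA`) episode that (i) lasts at least `min_sa_days`
#' days, (ii) starts inside the inclusion window and (iii) has a washout
#' period free of sickness absence (neither `FSA` nor `GSA`) during the
#' `washout_days` before its first day. That day becomes the person's
#' baseline; persons with no qualifying episode are excluded. The exposure at
#' baseline is taken from the covariate table's `exposure` column when
#' present; otherwise it is derived from the raw work records: a person is
#' exposed when any employer whose work record covers the baseline day holds
#' the agreement (`ia = 1` in `companies`), falling back to the covariate
#' table's `company_id` when no work record covers baseline.
#'
#' @param episodes Resolved episodes from [resolve_records()].
#' @param covariates Covariate table keyed by `person_id`; one row per person.
#'   Must cover every included person.
#' @param records Optional raw records (used for the concurrent-employer
#'   exposure rule and the baseline diagnosis group).
#' @param companies Optional company table with columns `company_id`, `ia`.
#' @param washout_days Length of the sickness-absence-free look-back window
#'   before baseline (days). Default 365.
#' @param min_sa_days Minimum length of the qualifying full-time
#'   sickness-absence episode, in days. Default 17 (strictly more than 16
#'   calendar days, counted from the first day).
#' @param inclusion_window Half-open calendar interval `c(start, end)` that
#'   must contain the baseline day. Default: unrestricted.
#' @param strict_washout If `TRUE` (default), any sickness-absence episode
#'   overlapping the washout window excludes the candidate, even one that
#'   started before the window; if `FALSE`, only episodes starting inside the
#'   window count.
#' @return A cohort tibble (class `rtw_cohort`) with `person_id`,
#'   `baseline_day`, `exposure`, `company_id` and the covariate columns, plus
#'   an `exclusions` attribute with counts per exclusion reason.
#' @export
extract_baseline_cohort <- function(episodes, covariates,
                                    records = NULL, companies = NULL,
                                    washout_days = 365, min_sa_days = 17,
                                    inclusion_window = c(-Inf, Inf),
                                    strict_washout = TRUE) {
  episodes <- .as_tbl(episodes)
  .assert_cols(episodes, c("person_id", "state", "start_day", "end_day"),
               "episodes")
  covariates <- .as_tbl(covariates)
  .assert_cols(covariates, "person_id", "covariates")
  n_ingested <- dplyr::n_distinct(episodes$person_id)

  sa <- episodes %>% filter(.data$state %in% c("FSA", "GSA"))
  cand <- episodes %>%
    filter(.data$state == "FSA",
           .data$end_day - .data$start_day >= min_sa_days,
           .data$start_day >= inclusion_window[1],
           .data$start_day < inclusion_window[2])

  if (nrow(cand)) {
    # washout check for every candidate against the person's SA episodes
    chk <- cand %>%
      mutate(.cand = dplyr::row_number(), w0 = .data$start_day - washout_days) %>%
      left_join(sa %>% rename(sa_start = "start_day", sa_end = "end_day") %>%
                  select("person_id", "sa_start", "sa_end", sa_state = "state"),
                by = "person_id", relationship = "many-to-many")
    if (strict_washout) {
      viol <- chk %>%
        filter(!is.na(.data$sa_start),
               .data$sa_end > .data$w0, .data$sa_start < .data$start_day)
    } else {
      viol <- chk %>%
        filter(!is.na(.data$sa_start),
               .data$sa_start >= .data$w0, .data$sa_start < .data$start_day)
    }
    cand <- cand %>%
      mutate(.cand = dplyr::row_number()) %>%
      anti_join(viol, by = ".cand")
  }
  n_washout <- 0L
  if (nrow(cand)) {
    qualifying <- cand %>%
      group_by(.data$person_id) %>%
      slice_min(.data$start_day, n = 1, with_ties = FALSE) %>%
      ungroup() %>%
      transmute(.data$person_id, baseline_day = .data$start_day)
  } else {
    qualifying <- tibble::tibble(person_id = episodes$person_id[0],
                                 baseline_day = numeric())
  }
  n_included <- nrow(qualifying)
  # persons having a long-enough in-window FSA episode but failing washout
  long_enough <- episodes %>%
    filter(.data$state == "FSA",
           .data$end_day - .data$start_day >= min_sa_days,
           .data$start_day >= inclusion_window[1],
           .data$start_day < inclusion_window[2]) %>%
    distinct(.data$person_id)
  n_washout <- nrow(long_enough) - n_included
  n_no_episode <- n_ingested - nrow(long_enough)

  missing_cov <- setdiff(qualifying$person_id, covariates$person_id)
  if (length(missing_cov)) {
    abort(paste0("missing covariate rows for included person(s): ",
                 paste(head(missing_cov, 5), collapse = ", "),
                 if (length(missing_cov) > 5) ", ..." else ""))
  }
  if (anyDuplicated(covariates$person_id)) {
    abort("covariate table must have one row per person_id")
  }

  cohort <- qualifying %>% left_join(covariates, by = "person_id")

  if (!"exposure" %in% names(cohort)) {
    if (is.null(companies)) {
      abort("no `exposure` column in covariates and no `companies` table given")
    }
    .assert_cols(companies, c("company_id", "ia"), "companies")
    cohort$exposure <- .exposure_at_baseline(cohort, records, companies)
  }
  if (!all(cohort$exposure %in% c(0, 1))) {
    abort("exposure must be binary 0/1")
  }

  # baseline diagnosis: prefer the sickness-absence record covering baseline
  if (!is.null(records) && "diagnosis_group" %in% names(records)) {
    base_dx <- .as_tbl(records) %>%
      filter(.data$record_type == "sickness_absence") %>%
      inner_join(cohort %>% select("person_id", "baseline_day"),
                 by = "person_id") %>%
      filter(.data$start_day <= .data$baseline_day,
             .data$end_day > .data$baseline_day) %>%
      group_by(.data$person_id) %>%
      slice_head(n = 1) %>%
      ungroup() %>%
      select("person_id", base_dx = "diagnosis_group")
    cohort <- cohort %>% left_join(base_dx, by = "person_id")
    if ("diagnosis_group" %in% names(cohort)) {
      cohort <- cohort %>%
        mutate(diagnosis_group = dplyr::coalesce(.data$base_dx,
                                                 .data$diagnosis_group)) %>%
        select(-"base_dx")
    } else {
      cohort <- cohort %>% rename(diagnosis_group = "base_dx")
    }
  }

  .new_rtw_tbl(cohort, "rtw_cohort",
               exclusions = tibble::tibble(
                 reason = c("no_qualifying_episode", "washout", "included"),
                 n = c(n_no_episode, n_washout, n_included)),
               washout_days = washout_days, min_sa_days = min_sa_days)
}

# exposure from concurrent employers at baseline ("exposed if either of the
# workplaces holds the agreement"), falling back to the covariate-table company
.exposure_at_baseline <- function(cohort, records, companies) {
  companies <- .as_tbl(companies)
  fallback <- rep(NA_real_, nrow(cohort))
  if ("company_id" %in% names(cohort)) {
    fallback <- companies$ia[match(cohort$company_id, companies$company_id)]
  }
  if (is.null(records)) {
    if (anyNA(fallback)) abort("cannot determine exposure: no records and no company match")
    return(as.numeric(fallback))
  }
  work_at_base <- .as_tbl(records) %>%
    filter(.data$record_type == "work") %>%
    inner_join(cohort %>% select("person_id", "baseline_day"),
               by = "person_id") %>%
    filter(.data$start_day <= .data$baseline_day,
           .data$end_day > .data$baseline_day) %>%
    left_join(companies %>% select("company_id", "ia"), by = "company_id") %>%
    group_by(.data$person_id) %>%
    summarise(exposure = as.numeric(any(.data$ia == 1)), .groups = "drop")
  out <- work_at_base$exposure[match(cohort$person_id, work_at_base$person_id)]
  out[is.na(out)] <- fallback[is.na(out)]
  if (anyNA(out)) abort("cannot determine exposure for some included persons")
  as.numeric(out)
}

#' Shift episode histories to baseline time and truncate follow-up
#'
#' Re-zeroes each included person's episode clock at their baseline day and
#' truncates follow-up at `horizon` days. Death (from the mortality register)
#' within observed follow-up replaces the remainder of the trajectory with an
#' absorbing `DEATH` episode extending to the horizon. The first state at time
#' 0 must be `FSA`.
#'
#' @param episodes Resolved calendar episodes ([resolve_records()]).
#' @param baseline Data frame with `person_id` and `baseline_day` (an
#'   `rtw_cohort` works); only these persons are kept.
#' @param horizon Follow-up horizon in days since baseline. Default 500.
#' @param death Optional data frame with `person_id`, `death_day` (calendar
#'   day; `NA` for alive). Deaths after the person's observed record coverage
#'   or after the horizon are ignored (right-censoring happens first).
#' @return A trajectories tibble (class `rtw_trajectories`) with columns
#'   `person_id`, `state`, `start_t`, `end_t` in days since baseline. The last
#'   episode per person ends at their censoring time (or at `horizon` when the
#'   person died or was fully observed).
#' @export
clock_reset_and_truncate <- function(episodes, baseline, horizon = 500,
                                     death = NULL) {
  episodes <- .as_tbl(episodes)
  .assert_cols(episodes, c("person_id", "state", "start_day", "end_day"),
               "episodes")
  baseline <- .as_tbl(baseline)
  .assert_cols(baseline, c("person_id", "baseline_day"), "baseline")

  traj <- episodes %>%
    inner_join(baseline %>% select("person_id", "baseline_day"),
               by = "person_id") %>%
    mutate(start_t = .data$start_day - .data$baseline_day,
           end_t = pmin(.data$end_day - .data$baseline_day, horizon)) %>%
    filter(.data$end_t > 0, .data$start_t < horizon) %>%
    mutate(start_t = pmax(.data$start_t, 0)) %>%
    select("person_id", "state", "start_t", "end_t") %>%
    arrange(.data$person_id, .data$start_t)

  if (!is.null(death) && any(!is.na(death$death_day))) {
    death <- .as_tbl(death) %>%
      select("person_id", "death_day") %>%
      inner_join(baseline %>% select("person_id", "baseline_day"),
                 by = "person_id") %>%
      mutate(death_t = .data$death_day - .data$baseline_day) %>%
      filter(!is.na(.data$death_t), .data$death_t < horizon, .data$death_t > 0)
    if (nrow(death)) {
      cens <- traj %>%
        group_by(.data$person_id) %>%
        summarise(censor_t = max(.data$end_t), .groups = "drop")
      death <- death %>%
        inner_join(cens, by = "person_id") %>%
        filter(.data$death_t <= .data$censor_t)  # died while under observation
      if (nrow(death)) {
        traj <- traj %>%
          left_join(death %>% select("person_id", "death_t"), by = "person_id") %>%
          filter(is.na(.data$death_t) | .data$start_t < .data$death_t) %>%
          mutate(end_t = ifelse(!is.na(.data$death_t),
                                pmin(.data$end_t, .data$death_t), .data$end_t)) %>%
          select(-"death_t")
        drows <- tibble::tibble(person_id = death$person_id, state = "DEATH",
                                start_t = death$death_t, end_t = horizon)
        traj <- bind_rows(traj, drows) %>%
          arrange(.data$person_id, .data$start_t)
      }
    }
  }

  first <- traj %>%
    group_by(.data$person_id) %>%
    slice_head(n = 1) %>%
    ungroup()
  bad <- first %>% filter(.data$state != "FSA" | .data$start_t != 0)
  if (nrow(bad)) {
    abort(paste0("internal consistency error: state at t = 0 is not FSA for ",
                 "person(s) ", paste(head(bad$person_id, 5), collapse = ", ")))
  }
  .new_rtw_tbl(traj, "rtw_trajectories", horizon = horizon)
}

#' Convert trajectories to counting-process transition records
#'
#' Produces one transition record per transient-state episode: the record's
#' `to_state` is the next episode's state, or `"CENSORED"` for a final episode
#' not ending in death. Absorbing `DEATH` episodes emit no record (death
#' appears as the `to_state` of the preceding episode).
#'
#' @param trajectories Trajectories from [clock_reset_and_truncate()].
#' @return A tibble with columns `person_id`, `from_state`, `entry_t`,
#'   `exit_t`, `to_state`.
#' @export
to_counting_process <- function(trajectories) {
  traj <- .as_tbl(trajectories)
  .assert_cols(traj, c("person_id", "state", "start_t", "end_t"),
               "trajectories")
  traj %>%
    arrange(.data$person_id, .data$start_t) %>%
    group_by(.data$person_id) %>%
    mutate(to_state = dplyr::lead(.data$state, default = .CENSORED)) %>%
    ungroup() %>%
    filter(.data$state != "DEATH") %>%
    transmute(.data$person_id, from_state = .data$state,
              entry_t = .data$start_t, exit_t = .data$end_t,
              .data$to_state)
}
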