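#' Negative-outcome-control diagnostic on pre-baseline histories
#'
#' The exposure cannot have caused anything before baseline, so after adequate
#' confounding adjustment the weighted pre-baseline state distributions should
#' be (nearly) identical across exposure arms. This computes, day by day over
#' the pre-baseline window, the unweighted and weighted state occupation
#' shares per arm and their between-arm differences, summarised per state as
#' the maximum absolute difference. The weights must be exactly the
#' main-analysis weights (they are reused, never refit). It is a diagnostic
#' report, not a hypothesis test: no p-value is attached.
#'
#' @param pre_trajectories Pre-baseline episodes with columns `person_id`,
#'   `state`, `start_t`, `end_t`, in days relative to baseline (negative
#'   times).
#' @param cohort An `rtw_cohort` (for the exposure arms).
#' @param weights The main analysis's [stabilized_weights()] result.
#' @return An object of class `rtw_negcontrol`: a list with `curves` (tibble
#'   `time`, `state`, `diff_unweighted`, `diff_weighted`), `summary` (tibble
#'   `state`, `max_abs_diff_unweighted`, `max_abs_diff_weighted`) and
#'   `n_missing` (included persons without pre-baseline data, excluded with a
#'   message).
#' @export
negative_control <- function(pre_trajectories, cohort, weights) {
  pre <- .as_tbl(pre_trajectories)
  .assert_cols(pre, c("person_id", "state", "start_t", "end_t"),
               "pre_trajectories")
  cohort <- .as_tbl(cohort)
  .assert_cols(cohort, c("person_id", "exposure"), "cohort")
  if (any(pre$end_t > 0)) {
    abort("pre-baseline trajectories must lie strictly before baseline (end_t <= 0)")
  }
  missing_pre <- setdiff(cohort$person_id, unique(pre$person_id))
  n_missing <- length(missing_pre)
  if (n_missing) {
    inform(paste0(n_missing, " included person(s) lack pre-baseline data ",
                  "and are excluded from the negative control"))
  }
  pre <- pre %>% semi_join(cohort, by = "person_id")
  a <- cohort$exposure[match(pre$person_id, cohort$person_id)]
  w <- .weights_for(pre$person_id, weights)

  t0 <- min(pre$start_t)
  grid <- seq(t0, -1)
  n_days <- length(grid)
  states <- sort(unique(pre$state))
  # per-day weighted occupation via difference arrays over the day grid
  day_idx <- function(t) t - t0 + 1L
  occ <- function(sel, wt) {
    denom <- numeric(n_days)
    add <- rowsum(c(wt[sel], -wt[sel]),
                  c(day_idx(pre$start_t[sel]), day_idx(pre$end_t[sel])))
    idx <- as.integer(rownames(add))
    ok <- idx >= 1 & idx <= n_days
    denom[idx[ok]] <- add[ok, 1L]
    cumsum(denom)
  }
  curves <- purrr::map_dfr(states, function(s) {
    res <- purrr::map(c(0, 1), function(arm) {
      sel_arm <- a == arm
      num_u <- occ(sel_arm & pre$state == s, rep(1, nrow(pre)))
      den_u <- occ(sel_arm, rep(1, nrow(pre)))
      num_w <- occ(sel_arm & pre$state == s, w)
      den_w <- occ(sel_arm, w)
      list(u = ifelse(den_u > 0, num_u / den_u, NA_real_),
           w = ifelse(den_w > 0, num_w / den_w, NA_real_))
    })
    tibble::tibble(time = grid, state = s,
                   diff_unweighted = res[[2]]$u - res[[1]]$u,
                   diff_weighted = res[[2]]$w - res[[1]]$w)
  })
  summary <- curves %>%
    group_by(.data$state) %>%
    summarise(max_abs_diff_unweighted = max(abs(.data$diff_unweighted),
                                            na.rm = TRUE),
              max_abs_diff_weighted = max(abs(.data$diff_weighted),
                                          na.rm = TRUE),
              .groups = "drop")
  structure(list(curves = curves, summary = summary, n_missing = n_missing),
            class = "rtw_negcontrol")
}

#' @export
print.rtw_negcontrol <- function(x, ...) {
  cat("Negative-outcome-control diagnostic (pre-baseline histories)\n")
  print(x$summary)
  invisible(x)
}
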