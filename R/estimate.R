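# Weighted Nelson-Aalen / Aalen-Johansen machinery.
#
# Episodes are half-open [entry_t, exit_t); a transition happens at exit_t.
# The risk set for an event at time s contains episodes with entry < s <= exit,
# so a person censored exactly at s still counts as at risk at s.

# weighted size of the risk set at each time in `s` (episodes of one state)
.risk_at <- function(s, entry, exit, w) {
  oe <- order(entry); ox <- order(exit)
  cw_entry <- c(0, cumsum(w[oe]))
  cw_exit <- c(0, cumsum(w[ox]))
  cw_entry[.count_lt(s, entry[oe]) + 1L] - cw_exit[.count_lt(s, exit[ox]) + 1L]
}

# all transition increments for one weighted sample.
# from_i/to_i are state indices (to_i = 0 means censored). Returns a list of
# vectors (time, from, to, inc, n_risk, n_event) sorted by time.
.transition_increments <- function(entry, exit, from_i, to_i, w, n_states,
                                   horizon = Inf) {
  tt <- ff <- jj <- vv <- rr <- ee <- list(); k <- 0L
  for (h in seq_len(n_states)) {
    rows <- which(from_i == h)
    if (!length(rows)) next
    ev <- rows[to_i[rows] > 0L & exit[rows] <= horizon]
    if (!length(ev)) next
    # weighted event mass per (to-state, time), via run-length aggregation
    key_t <- exit[ev]; key_j <- to_i[ev]
    o <- order(key_j, key_t)
    kj <- key_j[o]; kt <- key_t[o]; ws <- w[ev][o]
    last <- c(kj[-1L] != kj[-length(kj)] | kt[-1L] != kt[-length(kt)], TRUE)
    u_m <- diff(c(0, cumsum(ws)[last]))
    u_j <- kj[last]; u_t <- kt[last]
    risk <- .risk_at(u_t, entry[rows], exit[rows], w[rows])
    ok <- risk > 0
    k <- k + 1L
    tt[[k]] <- u_t[ok]; ff[[k]] <- rep(h, sum(ok)); jj[[k]] <- u_j[ok]
    vv[[k]] <- u_m[ok] / risk[ok]; rr[[k]] <- risk[ok]; ee[[k]] <- u_m[ok]
  }
  out <- list(time = unlist(tt) %||% numeric(), from = unlist(ff) %||% integer(),
              to = unlist(jj) %||% integer(), inc = unlist(vv) %||% numeric(),
              n_risk = unlist(rr) %||% numeric(), n_event = unlist(ee) %||% numeric())
  o <- order(out$time, out$from, out$to)
  lapply(out, `[`, o)
}

# product-integral: state occupation vector path over event times.
# inc: list as from .transition_increments. Returns list(times, path) where
# path is (n_event_times + 1) x n_states, row 1 = p0.
.aj_path <- function(inc, p0, n_states) {
  ut <- unique(inc$time)
  path <- matrix(0, length(ut) + 1L, n_states)
  path[1L, ] <- p0
  p <- p0
  if (length(ut)) {
    grp <- match(inc$time, ut)
    starts <- c(1L, which(diff(grp) > 0L) + 1L)
    ends <- c(starts[-1L] - 1L, length(grp))
    out_acc <- numeric(n_states)
    for (g in seq_along(ut)) {
      idx <- starts[g]:ends[g]
      p_new <- p
      out_acc[] <- 0
      for (k in idx) {
        hh <- inc$from[k]
        d <- inc$inc[k]
        out_acc[hh] <- out_acc[hh] + d
        move <- p[hh] * d
        p_new[hh] <- p_new[hh] - move
        jj <- inc$to[k]
        p_new[jj] <- p_new[jj] + move
      }
      if (any(out_acc > 1 + 1e-12)) {
        abort("invalid hazard increments: a transition-matrix row has a negative entry")
      }
      p <- p_new
      path[g + 1L, ] <- p
    }
  }
  list(times = ut, path = path)
}

# evaluate an .aj_path as a right-continuous step function on a grid
.aj_eval <- function(aj, grid) {
  aj$path[findInterval(grid, aj$times) + 1L, , drop = FALSE]
}

#' Weighted Nelson-Aalen cumulative transition hazard
#'
#' Estimates the cumulative hazard of one transition `from -> to` from
#' counting-process records, optionally weighted by per-person stabilised
#' weights. At each distinct event time \eqn{s}, the increment is the weighted
#' number of `from -> to` events at \eqn{s} divided by the weighted number at
#' risk in `from` just before \eqn{s}; tied events on the same day are summed.
#'
#' @param transitions Counting-process records from [to_counting_process()].
#' @param from,to State labels of the transition.
#' @param weights Optional weights: an [stabilized_weights()] result or a data
#'   frame with `person_id`, `weight`. `NULL` means unit weights.
#' @return A tibble (class `rtw_cumhaz`) with columns `time`, `n_risk`,
#'   `n_event` (both weighted), `increment` and `cumhaz`, plus `from`/`to`
#'   attributes. A transition with no events yields zero rows (an identically
#'   zero cumulative hazard).
#' @export
weighted_nelson_aalen <- function(transitions, from, to, weights = NULL) {
  transitions <- .as_tbl(transitions)
  .assert_cols(transitions,
               c("person_id", "from_state", "entry_t", "exit_t", "to_state"),
               "transitions")
  stopifnot(from %in% .RTW_TRANSIENT, to %in% .RTW_STATES, from != to)
  w <- .weights_for(transitions$person_id, weights)
  rows <- transitions$from_state == from
  ev <- rows & transitions$to_state == to
  ut <- sort(unique(transitions$exit_t[ev]))
  if (!length(ut)) {
    out <- tibble::tibble(time = numeric(), n_risk = numeric(),
                          n_event = numeric(), increment = numeric(),
                          cumhaz = numeric())
    return(.new_rtw_tbl(out, "rtw_cumhaz", from = from, to = to))
  }
  risk <- .risk_at(ut, transitions$entry_t[rows], transitions$exit_t[rows],
                   w[rows])
  mass <- rowsum(w[ev], transitions$exit_t[ev])
  n_event <- mass[match(as.character(ut), rownames(mass)), 1L]
  increment <- ifelse(risk > 0, n_event / risk, 0)
  out <- tibble::tibble(time = ut, n_risk = risk, n_event = n_event,
                        increment = increment, cumhaz = cumsum(increment))
  .new_rtw_tbl(out, "rtw_cumhaz", from = from, to = to)
}

# resolve a weights argument to a per-row weight vector aligned with person ids
.weights_for <- function(person_id, weights) {
  if (is.null(weights)) return(rep(1, length(person_id)))
  weights <- .as_tbl(weights)
  .assert_cols(weights, c("person_id", "weight"), "weights")
  w <- weights$weight[match(person_id, weights$person_id)]
  if (anyNA(w)) abort("weights do not cover every person in the transitions")
  w
}

#' Aalen-Johansen state occupation probabilities
#'
#' Plugs cumulative-hazard increments for all transitions of one arm into the
#' Aalen-Johansen product-integral
#' \eqn{\hat P(0, t) = \prod_{s \le t} (I + d\hat A(s))}, where the diagonal
#' increments are minus the row sums of the off-diagonal ones, and returns the
#' state occupation probability curve \eqn{p_0' \hat P(0, t)} evaluated as a
#' right-continuous step function on a day grid.
#'
#' @param hazards A list of [weighted_nelson_aalen()] results (one per
#'   transition), or a data frame with columns `from`, `to`, `time`,
#'   `increment`.
#' @param horizon Last day of the output grid.
#' @param p0 Initial distribution over `states`; default point mass on the
#'   first state.
#' @param states State labels; default the six-state space [rtw_states()].
#' @param arm Optional arm label stored on the result.
#' @return A curve tibble (class `rtw_curves`) with columns `arm`, `time`
#'   (days `0:horizon`) and one probability column per state. Rows sum to one.
#' @export
aalen_johansen <- function(hazards, horizon, p0 = NULL, states = rtw_states(),
                           arm = NA) {
  if (is.data.frame(hazards)) {
    inc_df <- .as_tbl(hazards)
    .assert_cols(inc_df, c("from", "to", "time", "increment"), "hazards")
  } else {
    inc_df <- purrr::map_dfr(hazards, function(h) {
      tibble::tibble(from = attr(h, "from"), to = attr(h, "to"),
                     time = h$time, increment = h$increment)
    })
  }
  if (is.null(p0)) p0 <- c(1, rep(0, length(states) - 1L))
  stopifnot(length(p0) == length(states), abs(sum(p0) - 1) < 1e-8)
  if (any(inc_df$increment < 0)) {
    abort("invalid hazard increments: a transition-matrix row has a negative entry")
  }
  inc_df <- inc_df %>% filter(.data$time <= horizon) %>% arrange(.data$time)
  inc <- list(time = inc_df$time, from = .state_index(inc_df$from, states),
              to = .state_index(inc_df$to, states), inc = inc_df$increment)
  aj <- .aj_path(inc, p0, length(states))
  grid <- 0:horizon
  mat <- .aj_eval(aj, grid)
  colnames(mat) <- states
  out <- tibble::as_tibble(mat)
  out <- bind_cols(tibble::tibble(arm = rep(arm, length(grid)), time = grid), out)
  .new_rtw_tbl(out, "rtw_curves", states = states, horizon = horizon, p0 = p0)
}

# fast single-arm engine used by estimate_arm_curves and the bootstrap:
# returns (horizon+1) x n_states occupation matrix
.arm_curve_matrix <- function(entry, exit, from_i, to_i, w, horizon,
                              n_states = length(.RTW_STATES)) {
  inc <- .transition_increments(entry, exit, from_i, to_i, w, n_states, horizon)
  aj <- .aj_path(inc, c(1, rep(0, n_states - 1L)), n_states)
  .aj_eval(aj, 0:horizon)
}

#' Per-arm weighted state probability curves
#'
#' Runs the weighted Nelson-Aalen / Aalen-Johansen estimator separately within
#' each exposure arm, using each person's stabilised weight, and returns both
#' arms' state occupation probability curves on a common day grid. This is the
#' group-wise equivalent of a weighted additive-hazards fit that adjusts only
#' for the exposure.
#'
#' @param transitions Counting-process records from [to_counting_process()].
#' @param cohort An `rtw_cohort` (needs `person_id`, `exposure`).
#' @param weights Optional [stabilized_weights()] result; `NULL` gives the
#'   unweighted (crude) estimator.
#' @param horizon Last day of the curve grid. Default 500.
#' @return An `rtw_curves` tibble with both arms stacked (`arm` 1 and 0).
#' @export
estimate_arm_curves <- function(transitions, cohort, weights = NULL,
                                horizon = 500) {
  transitions <- .as_tbl(transitions)
  cohort <- .as_tbl(cohort)
  .assert_cols(cohort, c("person_id", "exposure"), "cohort")
  arms <- cohort$exposure[match(transitions$person_id, cohort$person_id)]
  if (anyNA(arms)) {
    transitions <- transitions[!is.na(arms), , drop = FALSE]
    arms <- arms[!is.na(arms)]
  }
  if (!all(c(0, 1) %in% cohort$exposure)) {
    abort("both exposure arms must be non-empty")
  }
  w <- .weights_for(transitions$person_id, weights)
  from_i <- .state_index(transitions$from_state)
  to_i <- integer(nrow(transitions))
  cens <- transitions$to_state == .CENSORED
  to_i[!cens] <- .state_index(transitions$to_state[!cens])
  states <- .RTW_STATES
  out <- purrr::map_dfr(c(1, 0), function(a) {
    sel <- arms == a
    mat <- .arm_curve_matrix(transitions$entry_t[sel], transitions$exit_t[sel],
                             from_i[sel], to_i[sel], w[sel], horizon)
    colnames(mat) <- states
    bind_cols(tibble::tibble(arm = a, time = 0:horizon), tibble::as_tibble(mat))
  })
  .new_rtw_tbl(out, "rtw_curves", states = states, horizon = horizon,
               p0 = c(1, rep(0, length(states) - 1L)),
               weighted = !is.null(weights))
}

#' Effect curves: differences in state probabilities
#'
#' Computes \eqn{\theta(t) = \pi^1(t) - \pi^0(t)} per state from two state
#' probability curves on a common day grid. The state-wise differences sum to
#' zero at every time point.
#'
#' @param curve1 Curves for the exposed arm, or an `rtw_curves` object holding
#'   both arms (then `curve0` is ignored).
#' @param curve0 Curves for the unexposed arm.
#' @return An `rtw_effect` tibble with `time` and one difference column per
#'   state.
#' @export
effect_curve <- function(curve1, curve0 = NULL) {
  states <- attr(curve1, "states") %||% intersect(.RTW_STATES, names(curve1))
  if (is.null(curve0)) {
    stopifnot(all(c(0, 1) %in% curve1$arm))
    curve0 <- curve1 %>% filter(.data$arm == 0)
    curve1 <- curve1 %>% filter(.data$arm == 1)
  }
  if (nrow(curve1) != nrow(curve0) || any(curve1$time != curve0$time)) {
    abort("curves must share a common time grid")
  }
  diff_mat <- as.matrix(curve1[states]) - as.matrix(curve0[states])
  out <- bind_cols(tibble::tibble(time = curve1$time),
                   tibble::as_tibble(diff_mat))
  .new_rtw_tbl(out, "rtw_effect", states = states)
}

#' Expected length of stay
#'
#' Integrates state occupation probability curves over `[0, tau]` to get the
#' expected number of days spent in each state. The curve is a right-continuous
#' step function, so the integral is the exact sum
#' \eqn{\sum_k \pi(t_k) (t_{k+1} - t_k)} with the grid clipped at `tau`. Per
#' arm, the state-wise values sum to `tau`.
#'
#' @param curves An `rtw_curves` object (one or both arms).
#' @param tau Integration horizon in days; must not exceed the curve horizon.
#'   Default 365 (one year).
#' @return An `rtw_elos` tibble in long form: `arm`, `state`, `elos`. When both
#'   arms are present a `diff` column (arm 1 minus arm 0) is attached via
#'   [tidyr::pivot_wider()]-style columns `elos_1`, `elos_0`, `diff`.
#' @export
elos <- function(curves, tau = 365) {
  curves <- .as_tbl(curves)
  states <- attr(curves, "states") %||% intersect(.RTW_STATES, names(curves))
  if (!"arm" %in% names(curves)) curves$arm <- NA
  horizon <- max(curves$time)
  if (tau > horizon) abort("`tau` exceeds the curve horizon")
  long <- curves %>%
    group_by(.data$arm) %>%
    group_modify(function(df, key) {
      tt <- df$time
      widths <- pmin(c(tt[-1], max(tt)), tau) - pmin(tt, tau)
      vals <- colSums(as.matrix(df[states]) * widths)
      tibble::tibble(state = states, elos = unname(vals))
    }) %>%
    ungroup()
  if (all(c(0, 1) %in% long$arm)) {
    wide <- long %>%
      tidyr::pivot_wider(names_from = "arm", values_from = "elos",
                         names_prefix = "elos_") %>%
      mutate(diff = .data$elos_1 - .data$elos_0,
             state = factor(.data$state, levels = states)) %>%
      arrange(.data$state) %>%
      mutate(state = as.character(.data$state))
    return(.new_rtw_tbl(wide, "rtw_elos", tau = tau))
  }
  .new_rtw_tbl(long, "rtw_elos", tau = tau)
}
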