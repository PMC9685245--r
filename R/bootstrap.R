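#' Company-clustered bootstrap confidence bands
#'
#' Resamples whole companies with replacement (individuals travel with their
#' company; duplicated companies count as fresh clusters) and, inside every
#' replicate, re-fits the propensity model, recomputes the stabilised weights,
#' and re-estimates the per-arm curves, the effect curves \eqn{\theta(t)} and
#' the expected-length-of-stay differences. Percentile (default) or
#' normal-approximation confidence bands are returned per state and time.
#' Replicates in which one exposure arm is empty are redrawn (the redraw count
#' is reported). Replicate `r` uses a random stream derived from
#' `(seed, r)`, so results do not depend on execution order.
#'
#' @param cohort An `rtw_cohort` (with `company_id` and the confounders).
#' @param transitions Counting-process records of the same persons.
#' @param adjustment_set Confounders for the propensity refit in each
#'   replicate.
#' @param B Number of bootstrap replicates. Default 1000.
#' @param seed Integer seed (mandatory).
#' @param horizon Curve horizon in days.
#' @param tau Expected-length-of-stay horizon in days.
#' @param conf_level Confidence level for the bands. Default 0.95.
#' @param method `"percentile"` (default) or `"normal"`.
#' @param keep_replicates If `TRUE`, the replicate-level \eqn{\theta(t)}
#'   array and ELOS-difference matrix are returned.
#' @param weighted If `FALSE`, replicates skip the propensity refit and use
#'   unit weights (crude estimator).
#' @return An object of class `rtw_boot`: a list with `theta_bands` (tibble
#'   `time`, `state`, `estimate`, `lower`, `upper`), `elos_bands` (tibble
#'   `state`, `estimate`, `lower`, `upper`), `B`, `seed`, `redraws` and
#'   optionally the replicates.
#' @export
cluster_bootstrap <- function(cohort, transitions, adjustment_set = character(),
                              B = 1000, seed, horizon = 500, tau = 365,
                              conf_level = 0.95,
                              method = c("percentile", "normal"),
                              keep_replicates = FALSE, weighted = TRUE) {
  method <- match.arg(method)
  if (missing(seed) || !.is_scalar_number(seed)) {
    abort("`seed` is mandatory and must be a single integer")
  }
  stopifnot(B >= 2, tau <= horizon)
  cohort <- .as_tbl(cohort)
  .assert_cols(cohort, c("person_id", "exposure", "company_id"), "cohort")
  transitions <- .as_tbl(transitions)
  n_comp_per_arm <- cohort %>%
    distinct(.data$company_id, .data$exposure) %>%
    count(.data$exposure)
  if (nrow(n_comp_per_arm) < 2 || any(n_comp_per_arm$n < 2)) {
    abort("need at least 2 companies per exposure arm for the clustered bootstrap")
  }

  # --- precomputation shared by all replicates -------------------------------
  for (v in adjustment_set) {
    if (is.character(cohort[[v]])) cohort[[v]] <- factor(cohort[[v]])
  }
  form <- if (length(adjustment_set)) reformulate(adjustment_set) else ~1
  X <- model.matrix(form, data = cohort)
  A <- cohort$exposure
  companies <- unique(cohort$company_id)
  rows_by_company <- split(seq_len(nrow(cohort)), match(cohort$company_id,
                                                        companies))
  tr_person <- match(transitions$person_id, cohort$person_id)
  if (anyNA(tr_person)) {
    keep <- !is.na(tr_person)
    transitions <- transitions[keep, , drop = FALSE]
    tr_person <- tr_person[keep]
  }
  tr_rows_by_person <- split(seq_len(nrow(transitions)), tr_person)
  tr_rows <- vector("list", nrow(cohort))
  tr_rows[as.integer(names(tr_rows_by_person))] <- tr_rows_by_person
  tr_count <- lengths(tr_rows)
  entry <- transitions$entry_t
  exit <- transitions$exit_t
  from_i <- .state_index(transitions$from_state)
  to_i <- integer(nrow(transitions))
  cens <- transitions$to_state == .CENSORED
  to_i[!cens] <- .state_index(transitions$to_state[!cens])
  states <- .RTW_STATES
  ns <- length(states)
  grid <- 0:horizon

  estimate_once <- function(person_idx) {
    Xb <- X[person_idx, , drop = FALSE]
    Ab <- A[person_idx]
    if (weighted && length(adjustment_set)) {
      fit <- suppressWarnings(
        stats::glm.fit(Xb, Ab, family = binomial(), control = list(maxit = 50)))
      p <- pmin(pmax(fit$fitted.values, 1e-12), 1 - 1e-12)
      pbar <- mean(Ab)
      w_person <- ifelse(Ab == 1, pbar / p, (1 - pbar) / (1 - p))
    } else {
      w_person <- rep(1, length(person_idx))
    }
    rows <- unlist(tr_rows[person_idx], use.names = FALSE)
    w_row <- rep(w_person, tr_count[person_idx])
    a_row <- rep(Ab, tr_count[person_idx])
    theta <- matrix(NA_real_, length(grid), ns)
    el <- numeric(ns)
    for (a in c(1, 0)) {
      sel <- rows[a_row == a]
      wsel <- w_row[a_row == a]
      mat <- .arm_curve_matrix(entry[sel], exit[sel], from_i[sel], to_i[sel],
                               wsel, horizon, ns)
      if (a == 1) {
        theta <- mat; el <- colSums(mat[seq_len(tau), , drop = FALSE])
      } else {
        theta <- theta - mat
        el <- el - colSums(mat[seq_len(tau), , drop = FALSE])
      }
    }
    list(theta = theta, elos = el)
  }

  point <- estimate_once(seq_len(nrow(cohort)))

  nc <- length(companies)
  theta_rep <- array(NA_real_, c(B, length(grid), ns))
  elos_rep <- matrix(NA_real_, B, ns)
  redraws <- 0L
  for (r in seq_len(B)) {
    withr::with_seed(.substream_seed(seed, r), {
      repeat {
        comp_idx <- sample.int(nc, nc, replace = TRUE)
        person_idx <- unlist(rows_by_company[comp_idx], use.names = FALSE)
        if (length(unique(A[person_idx])) == 2L) break
        redraws <- redraws + 1L
      }
      est <- estimate_once(person_idx)
      theta_rep[r, , ] <- est$theta
      elos_rep[r, ] <- est$elos
    })
  }

  alpha <- (1 - conf_level) / 2
  band <- function(est, reps) {
    if (method == "percentile") {
      lo <- apply(reps, 2, quantile, probs = alpha, na.rm = TRUE)
      hi <- apply(reps, 2, quantile, probs = 1 - alpha, na.rm = TRUE)
    } else {
      se <- apply(reps, 2, sd, na.rm = TRUE)
      z <- qnorm(1 - alpha)
      lo <- est - z * se
      hi <- est + z * se
    }
    list(lower = lo, upper = hi)
  }
  theta_bands <- purrr::map_dfr(seq_len(ns), function(j) {
    b <- band(point$theta[, j], theta_rep[, , j])
    tibble::tibble(time = grid, state = states[j],
                   estimate = point$theta[, j], lower = b$lower,
                   upper = b$upper)
  })
  eb <- band(point$elos, elos_rep)
  elos_bands <- tibble::tibble(state = states, estimate = point$elos,
                               lower = eb$lower, upper = eb$upper)
  out <- list(theta_bands = theta_bands, elos_bands = elos_bands,
              B = B, seed = seed, redraws = redraws,
              conf_level = conf_level, method = method, tau = tau,
              horizon = horizon)
  if (keep_replicates) {
    out$theta_replicates <- theta_rep
    out$elos_replicates <- elos_rep
  }
  structure(out, class = "rtw_boot")
}

#' @export
print.rtw_boot <- function(x, ...) {
  cat(sprintf(
    "Company-clustered bootstrap: B = %d (%s %.0f%% bands, %d redraws)\n",
    x$B, x$method, 100 * x$conf_level, x$redraws))
  peak <- x$theta_bands %>%
    filter(.data$state == "WORK") %>%
    slice_max(.data$estimate, n = 1, with_ties = FALSE)
  cat(sprintf("  peak WORK effect %.4f at day %d (%.4f, %.4f)\n",
              peak$estimate, peak$time, peak$lower, peak$upper))
  invisible(x)
}
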