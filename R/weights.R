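#' Fit a propensity model for the baseline exposure
#'
#' Fits a maximum-likelihood logistic regression of the binary baseline
#' exposure on the named confounders (main effects, indicator coding of
#' categorical variables). Character confounders are coded as factors; factors
#' keep their existing level order, so the first level is the reference.
#' Perfect or near-perfect separation (fitted probabilities numerically 0 or
#' 1) is reported as a positivity problem rather than silently returned.
#'
#' @param cohort An `rtw_cohort` (or any data frame with `person_id`,
#'   `exposure` and the confounder columns).
#' @param adjustment_set Character vector of confounder column names. An empty
#'   set fits an intercept-only model, so every fitted score equals the
#'   observed exposure prevalence.
#' @return An object of class `rtw_propensity`: a list with `scores` (tibble
#'   `person_id`, `exposure`, `pscore`), the underlying `fit`, and the
#'   `adjustment_set`. Supports [tidy()] and [glance()].
#' @export
fit_propensity <- function(cohort, adjustment_set = character()) {
  cohort <- .as_tbl(cohort)
  .assert_cols(cohort, c("person_id", "exposure"), "cohort")
  missing <- setdiff(adjustment_set, names(cohort))
  if (length(missing)) {
    abort(paste0("adjustment_set names not in cohort: ",
                 paste(missing, collapse = ", ")))
  }
  if (min(table(factor(cohort$exposure, levels = c(0, 1)))) < 2) {
    abort("need at least 2 persons in each exposure arm")
  }
  df <- cohort[, c("exposure", adjustment_set), drop = FALSE]
  for (v in adjustment_set) {
    if (is.character(df[[v]])) df[[v]] <- factor(df[[v]])
    if (anyNA(df[[v]])) {
      abort(paste0("missing confounder values in `", v,
                   "`; missing values are rejected, not imputed"))
    }
  }
  # constant confounders (e.g. the stratifying variable of a subgroup refit)
  # carry no information and would break the indicator coding
  constant <- adjustment_set[vapply(adjustment_set, function(v)
    dplyr::n_distinct(df[[v]]) < 2L, logical(1))]
  if (length(constant)) {
    inform(paste0("dropping constant confounder(s) from the propensity model: ",
                  paste(constant, collapse = ", ")))
    adjustment_set <- setdiff(adjustment_set, constant)
  }
  form <- if (length(adjustment_set)) {
    reformulate(adjustment_set, "exposure")
  } else {
    exposure ~ 1
  }
  fit <- withCallingHandlers(
    glm(form, data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        abort(paste0("(near-)perfect separation in the propensity model: ",
                     "some fitted exposure probabilities are numerically 0 ",
                     "or 1 (positivity violation). Consider coarsening the ",
                     "adjustment set."))
      }
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged) abort("propensity model did not converge")
  p <- unname(fit$fitted.values)
  eps <- 1e-10
  if (any(p <= eps | p >= 1 - eps)) {
    abort(paste0("fitted propensity scores numerically 0 or 1 (positivity ",
                 "violation); consider coarsening the adjustment set"))
  }
  structure(
    list(scores = tibble::tibble(person_id = cohort$person_id,
                                 exposure = cohort$exposure, pscore = p),
         fit = fit, adjustment_set = adjustment_set),
    class = "rtw_propensity")
}

#' @export
print.rtw_propensity <- function(x, ...) {
  cat("Propensity model (logistic):", length(x$adjustment_set),
      "confounder(s)\n")
  cat("  adjustment set:",
      if (length(x$adjustment_set)) paste(x$adjustment_set, collapse = ", ")
      else "(intercept only)", "\n")
  cat(sprintf("  n = %d, marginal P(A=1) = %.3f\n", nrow(x$scores),
              mean(x$scores$exposure)))
  invisible(x)
}

#' Stabilised inverse-probability-of-treatment weights
#'
#' Builds baseline stabilised IPT weights from fitted propensity scores:
#' \eqn{w_i = \bar p / p_i} for exposed persons and
#' \eqn{w_i = (1 - \bar p)/(1 - p_i)} for unexposed, where \eqn{\bar p} is the
#' marginal exposure prevalence. With an intercept-only propensity model all
#' weights are exactly 1; under a saturated model the within-arm mean weight
#' is exactly 1.
#'
#' @param scores An `rtw_propensity` object, or a numeric vector of propensity
#'   scores in (0, 1).
#' @param exposure Binary exposure vector (only needed when `scores` is
#'   numeric).
#' @param truncation_quantile Optional symmetric truncation: weights are capped
#'   at their `truncation_quantile` and `1 - truncation_quantile` quantiles.
#'   Default `NULL` (no truncation).
#' @param person_id Optional ids when `scores` is numeric.
#' @return An `rtw_weights` tibble with `person_id`, `exposure`, `pscore`,
#'   `weight`, carrying a `diagnostics` attribute (mean and maximum weight,
#'   effective sample size per arm, truncation bounds). Supports [glance()].
#' @export
stabilized_weights <- function(scores, exposure = NULL,
                               truncation_quantile = NULL, person_id = NULL) {
  if (inherits(scores, "rtw_propensity")) {
    person_id <- scores$scores$person_id
    exposure <- scores$scores$exposure
    p <- scores$scores$pscore
  } else {
    p <- as.numeric(scores)
    if (is.null(exposure)) abort("`exposure` is required with numeric scores")
    if (is.null(person_id)) person_id <- seq_along(p)
  }
  if (any(p <= 0 | p >= 1)) {
    abort("propensity scores must lie strictly inside (0, 1) (positivity)")
  }
  stopifnot(length(exposure) == length(p), all(exposure %in% c(0, 1)))
  pbar <- mean(exposure)
  w <- ifelse(exposure == 1, pbar / p, (1 - pbar) / (1 - p))
  trunc_bounds <- NULL
  if (!is.null(truncation_quantile)) {
    stopifnot(truncation_quantile > 0, truncation_quantile < 0.5)
    trunc_bounds <- quantile(w, c(truncation_quantile, 1 - truncation_quantile))
    w <- pmin(pmax(w, trunc_bounds[1]), trunc_bounds[2])
    inform(sprintf("weights truncated at quantiles [%.3g, %.3g] = [%.4g, %.4g]",
                   truncation_quantile, 1 - truncation_quantile,
                   trunc_bounds[1], trunc_bounds[2]))
  }
  ess <- function(x) sum(x)^2 / sum(x^2)
  diagnostics <- list(
    mean_weight = mean(w), max_weight = max(w),
    ess_exposed = ess(w[exposure == 1]), ess_unexposed = ess(w[exposure == 0]),
    n = length(w), marginal = pbar, truncation = trunc_bounds)
  .new_rtw_tbl(tibble::tibble(person_id = person_id, exposure = exposure,
                              pscore = p, weight = w),
               "rtw_weights", diagnostics = diagnostics)
}

#' Covariate balance before and after weighting
#'
#' For each level of each confounder, reports the unweighted and weighted
#' shares per exposure arm and the standardised mean difference (SMD) of the
#' level indicator before and after weighting, mirroring the four-column
#' unweighted/IPTW descriptive-table layout. Weighted shares per confounder
#' sum to one within each arm.
#'
#' @param cohort An `rtw_cohort`.
#' @param weights An `rtw_weights` tibble aligned with the cohort (unit
#'   weights when `NULL`).
#' @param confounders Confounder columns to tabulate; defaults to every
#'   non-identifier categorical column.
#' @return An `rtw_balance` tibble with one row per confounder level.
#' @export
balance_table <- function(cohort, weights = NULL, confounders = NULL) {
  cohort <- .as_tbl(cohort)
  .assert_cols(cohort, c("person_id", "exposure"), "cohort")
  if (is.null(confounders)) {
    skip <- c("person_id", "exposure", "company_id", "baseline_day")
    confounders <- names(cohort)[vapply(cohort, function(x)
      is.character(x) || is.factor(x), logical(1))]
    confounders <- setdiff(confounders, skip)
  }
  w <- if (is.null(weights)) rep(1, nrow(cohort)) else
    .weights_for(cohort$person_id, weights)
  a <- cohort$exposure
  smd <- function(m1, m0, v1, v0) {
    den <- sqrt((v1 + v0) / 2)
    ifelse(den > 0, (m1 - m0) / den, 0)
  }
  rows <- purrr::map_dfr(confounders, function(v) {
    x <- as.character(cohort[[v]])
    lv <- if (is.factor(cohort[[v]])) levels(cohort[[v]]) else sort(unique(x))
    purrr::map_dfr(lv, function(l) {
      ind <- as.numeric(x == l)
      m1u <- mean(ind[a == 1]); m0u <- mean(ind[a == 0])
      m1w <- sum(w[a == 1] * ind[a == 1]) / sum(w[a == 1])
      m0w <- sum(w[a == 0] * ind[a == 0]) / sum(w[a == 0])
      v1 <- m1u * (1 - m1u); v0 <- m0u * (1 - m0u)
      tibble::tibble(
        confounder = v, level = l,
        n_unexposed = sum(a == 0 & ind == 1), n_exposed = sum(a == 1 & ind == 1),
        p_unexposed = m0u, p_exposed = m1u,
        p_unexposed_weighted = m0w, p_exposed_weighted = m1w,
        smd_unweighted = smd(m1u, m0u, v1, v0),
        smd_weighted = smd(m1w, m0w, v1, v0))
    })
  })
  .new_rtw_tbl(rows, "rtw_balance")
}
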