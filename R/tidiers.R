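# broom-style tidiers for the package's result objects

#' Tidy state probability curves into long form
#'
#' @param curves An `rtw_curves` tibble (wide, one column per state).
#' @return A tibble with columns `arm`, `time`, `state`, `prob`.
#' @export
tidy_curves <- function(curves) {
  states <- attr(curves, "states") %||% intersect(.RTW_STATES, names(curves))
  .as_tbl(curves) %>%
    tidyr::pivot_longer(dplyr::all_of(states), names_to = "state",
                        values_to = "prob") %>%
    mutate(state = factor(.data$state, levels = states))
}

#' @method tidy rtw_curves
#' @export
tidy.rtw_curves <- function(x, ...) tidy_curves(x)

#' @method tidy rtw_effect
#' @export
tidy.rtw_effect <- function(x, ...) {
  states <- attr(x, "states") %||% setdiff(names(x), "time")
  .as_tbl(x) %>%
    tidyr::pivot_longer(dplyr::all_of(states), names_to = "state",
                        values_to = "estimate")
}

#' @method tidy rtw_elos
#' @export
tidy.rtw_elos <- function(x, ...) .as_tbl(x)

#' @method tidy rtw_propensity
#' @export
tidy.rtw_propensity <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @method glance rtw_propensity
#' @export
glance.rtw_propensity <- function(x, ...) {
  tibble::tibble(n = nrow(x$scores), marginal = mean(x$scores$exposure),
                 null.deviance = x$fit$null.deviance,
                 deviance = x$fit$deviance, aic = x$fit$aic,
                 df.residual = x$fit$df.residual)
}

#' @method glance rtw_weights
#' @export
glance.rtw_weights <- function(x, ...) {
  d <- attr(x, "diagnostics")
  tibble::tibble(n = d$n, marginal = d$marginal, mean_weight = d$mean_weight,
                 max_weight = d$max_weight, ess_exposed = d$ess_exposed,
                 ess_unexposed = d$ess_unexposed)
}

#' @method tidy rtw_boot
#' @export
tidy.rtw_boot <- function(x, ...) {
  x$theta_bands
}

#' @method glance rtw_boot
#' @export
glance.rtw_boot <- function(x, ...) {
  tibble::tibble(B = x$B, seed = x$seed, redraws = x$redraws,
                 conf_level = x$conf_level, method = x$method)
}

#' @method tidy rtw_negcontrol
#' @export
tidy.rtw_negcontrol <- function(x, ...) x$summary

#' @method tidy rtw_balance
#' @export
tidy.rtw_balance <- function(x, ...) .as_tbl(x)
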