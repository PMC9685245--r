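# Plotting is isolated here; the analysis core never renders anything.

.STATE_LABELS <- c(FSA = "Full-time SA", GSA = "Graded SA", WORK = "Work",
                   NONEMP = "Non-employment", EDU = "Education",
                   DEATH = "Death")

.STATE_FILL <- c(FSA = "#d95f02", GSA = "#e6ab02", WORK = "#1b9e77",
                 NONEMP = "#7570b3", EDU = "#66a61e", DEATH = "#666666")

.save_maybe <- function(p, file, width = 8, height = 5) {
  if (!is.null(file)) ggplot2::ggsave(file, p, width = width, height = height,
                                      dpi = 150)
  p
}

#' Stacked state probability plot
#'
#' Stacked area chart of state occupation probabilities over follow-up: one
#' band per state, bands summing to one at every day. Works for a single-arm,
#' a pooled (both-arm, unweighted) or a per-arm curve set; with two arms the
#' plot is facetted by arm.
#'
#' @param curves An `rtw_curves` tibble.
#' @param file Optional path; when given the figure is also written to disk.
#' @param state_order Order of the bands, bottom to top.
#' @param palette Named fill colours per state.
#' @return The ggplot object, invisibly when written to file.
#' @export
stacked_probability_plot <- function(curves, file = NULL,
                                     state_order = rev(rtw_states()),
                                     palette = .STATE_FILL) {
  long <- tidy_curves(curves) %>%
    mutate(state = factor(.data$state, levels = state_order))
  p <- ggplot(long, aes(x = .data$time, y = .data$prob, fill = .data$state)) +
    geom_area(position = "stack") +
    scale_fill_manual(values = palette, labels = .STATE_LABELS,
                      name = NULL) +
    scale_y_continuous(expand = c(0, 0)) +
    scale_x_continuous(expand = c(0, 0)) +
    labs(x = "Days since entering full-time sickness absence",
         y = "State probability") +
    theme_minimal()
  if (length(unique(long$arm)) > 1L) {
    p <- p + facet_wrap(~arm, labeller = label_both)
  }
  .save_maybe(p, file)
}

#' @method autoplot rtw_curves
#' @export
autoplot.rtw_curves <- function(object, ...) stacked_probability_plot(object)

#' Effect-curve plot
#'
#' Differences in state probabilities over time, one panel per state, with
#' bootstrap confidence ribbons when a [cluster_bootstrap()] result is given.
#'
#' @param object An `rtw_effect` tibble or an `rtw_boot` result.
#' @param states States to display (death differences are usually negligible).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rtw_effect
#' @export
autoplot.rtw_effect <- function(object, states = rtw_states(TRUE), ...) {
  long <- tidy(object) %>% filter(.data$state %in% states)
  ggplot(long, aes(x = .data$time, y = .data$estimate)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_line(colour = "#1b9e77") +
    facet_wrap(~state, labeller = as_labeller(.STATE_LABELS)) +
    labs(x = "Days since entering full-time sickness absence",
         y = "Difference in state probability") +
    theme_minimal()
}

#' @rdname autoplot.rtw_effect
#' @method autoplot rtw_boot
#' @export
autoplot.rtw_boot <- function(object, states = rtw_states(TRUE), ...) {
  long <- object$theta_bands %>% filter(.data$state %in% states)
  ggplot(long, aes(x = .data$time, y = .data$estimate)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    geom_ribbon(aes(ymin = .data$lower, ymax = .data$upper),
                fill = "#1b9e77", alpha = 0.25) +
    geom_line(colour = "#1b9e77") +
    facet_wrap(~state, labeller = as_labeller(.STATE_LABELS)) +
    labs(x = "Days since entering full-time sickness absence",
         y = "Difference in state probability") +
    theme_minimal()
}

#' Sequence plot of individual multistate histories
#'
#' One horizontal coloured bar per person showing their state over follow-up,
#' optionally grouped into panels (e.g. by industry) and ordered by a stated
#' rule. Large cohorts are thinned deterministically to `max_rows` per panel
#' (evenly spaced after ordering).
#'
#' @param trajectories An `rtw_trajectories` tibble.
#' @param group Optional data frame with `person_id` and a `group` column (or
#'   an `rtw_cohort` column name passed via `group_var`).
#' @param group_var When `group` is a cohort-like table, the column to panel
#'   by.
#' @param max_rows Maximum bars per panel.
#' @param order_by Ordering rule: `"first_work"` (day of first entry into
#'   work; persons who never work sort last) or `"person_id"`.
#' @param file Optional output path.
#' @return A ggplot object.
#' @export
sequence_plot <- function(trajectories, group = NULL, group_var = NULL,
                          max_rows = 200, order_by = c("first_work", "person_id"),
                          file = NULL) {
  order_by <- match.arg(order_by)
  traj <- .as_tbl(trajectories)
  .assert_cols(traj, c("person_id", "state", "start_t", "end_t"),
               "trajectories")
  if (!is.null(group)) {
    group <- .as_tbl(group)
    if (!is.null(group_var)) {
      group <- group %>% select("person_id", group = dplyr::all_of(group_var))
    }
    .assert_cols(group, c("person_id", "group"), "group")
    traj <- traj %>% inner_join(group, by = "person_id")
  } else {
    traj$group <- "all"
  }
  ord <- traj %>%
    group_by(.data$group, .data$person_id) %>%
    summarise(first_work = min(c(Inf, .data$start_t[.data$state == "WORK"])),
              .groups = "drop")
  if (order_by == "first_work") {
    ord <- ord %>% arrange(.data$group, .data$first_work, .data$person_id)
  } else {
    ord <- ord %>% arrange(.data$group, .data$person_id)
  }
  ord <- ord %>%
    group_by(.data$group) %>%
    mutate(rank = dplyr::row_number(), n = dplyr::n()) %>%
    filter(.data$n <= max_rows |
             .data$rank %in% unique(round(seq(1, .data$n[1],
                                              length.out = max_rows)))) %>%
    mutate(row = dplyr::row_number()) %>%
    ungroup()
  df <- traj %>%
    inner_join(ord %>% select("person_id", "group", "row"),
               by = c("person_id", "group")) %>%
    mutate(state = factor(.data$state, levels = rtw_states()))
  p <- ggplot(df) +
    geom_rect(aes(xmin = .data$start_t, xmax = .data$end_t,
                  ymin = .data$row - 0.5, ymax = .data$row + 0.5,
                  fill = .data$state)) +
    scale_fill_manual(values = .STATE_FILL, labels = .STATE_LABELS,
                      name = NULL, drop = FALSE) +
    facet_wrap(~group, scales = "free_y") +
    labs(x = "Days since entering full-time sickness absence", y = NULL) +
    theme_minimal() +
    theme(axis.text.y = element_blank(), panel.grid.major.y = element_blank())
  .save_maybe(p, file, width = 9, height = 6)
}

#' Covariate balance (love) plot
#'
#' Standardised mean differences per confounder level before and after
#' weighting.
#'
#' @param object An `rtw_balance` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot rtw_balance
#' @export
autoplot.rtw_balance <- function(object, ...) {
  long <- object %>%
    mutate(label = paste0(.data$confounder, ": ", .data$level)) %>%
    tidyr::pivot_longer(c("smd_unweighted", "smd_weighted"),
                        names_to = "set", values_to = "smd") %>%
    mutate(set = ifelse(.data$set == "smd_unweighted", "unweighted", "IPTW"))
  ggplot(long, aes(x = abs(.data$smd), y = .data$label, colour = .data$set)) +
    geom_vline(xintercept = 0.1, linetype = 2, colour = "grey60") +
    geom_point() +
    labs(x = "|standardised mean difference|", y = NULL, colour = NULL) +
    theme_minimal()
}
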