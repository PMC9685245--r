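#' Analysis configuration
#'
#' Normalises and validates the configuration that drives
#' [run_full_analysis()]. A configuration either names input CSV files
#' (`records`, `covariates`, `companies`) or carries a `simulate` block (the
#' arguments of [sim_config()]); it may be given as a list or as a path to a
#' YAML file with the same keys.
#'
#' @param config A list or a YAML file path.
#' @return A validated config list of class `rtw_analysis_config`.
#' @export
analysis_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(
    records = NULL, covariates = NULL, companies = NULL,
    simulate = NULL,
    washout_days = 365, min_sa_days = 17,
    horizon_days = 500, elos_tau = 365,
    adjustment_set = c("sex", "age_group", "education", "inclusion_year",
                       "industry", "company_size", "region"),
    subgroup = NULL,           # list(sex=, diagnosis_group=, industry=,
                               #      exclude_pregnancy=)
    refit_weights_in_subgroup = TRUE,
    bootstrap = list(enabled = FALSE, B = 1000, seed = NULL),
    negative_control = TRUE,
    inclusion_window = NULL,
    seed = 1L,
    outdir = NULL
  )
  cfg <- utils::modifyList(defaults, config)
  if (cfg$elos_tau > cfg$horizon_days) {
    abort("`elos_tau` must not exceed `horizon_days`")
  }
  if (is.null(cfg$simulate) && (is.null(cfg$records) || is.null(cfg$covariates))) {
    abort("config needs either input paths (`records`, `covariates`) or a `simulate` block")
  }
  if (!is.null(cfg$subgroup)) {
    allowed <- c("sex", "diagnosis_group", "industry", "exclude_pregnancy")
    bad <- setdiff(names(cfg$subgroup), allowed)
    if (length(bad)) {
      abort(paste0("unknown subgroup filter(s): ", paste(bad, collapse = ", ")))
    }
  }
  structure(cfg, class = "rtw_analysis_config")
}

.read_csv_quiet <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

.write_csv_maybe <- function(df, outdir, name) {
  if (!is.null(outdir)) {
    readr::write_csv(.as_tbl(df), file.path(outdir, name))
  }
  invisible(df)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage `", name, "` failed: ", conditionMessage(e)),
          parent = e)
  })
}

#' Run the full analysis end-to-end
#'
#' Orchestrates the whole pipeline: simulate or ingest raw registry records,
#' resolve them into episodes, extract the baseline cohort (optionally
#' restricted to a subgroup), reset clocks and build counting-process data,
#' fit the propensity model and stabilised weights, report balance, estimate
#' per-arm state probability curves, effect curves and expected length of
#' stay, optionally attach company-clustered bootstrap bands and the
#' pre-baseline negative-control diagnostic, and write all stage outputs plus
#' a machine-readable run manifest when `outdir` is set. Any stage failure
#' aborts with the stage name; outputs of completed stages are already on
#' disk.
#'
#' @param config An [analysis_config()], a plain list, or a YAML path.
#' @return An `rtw_analysis` bundle (list) with all intermediate and final
#'   objects, invisibly when `outdir` is set.
#' @export
run_full_analysis <- function(config) {
  cfg <- if (inherits(config, "rtw_analysis_config")) config else
    analysis_config(config)
  if (!is.null(cfg$outdir) && !dir.exists(cfg$outdir)) {
    dir.create(cfg$outdir, recursive = TRUE)
  }
  res <- list(config = cfg)
  manifest <- list(seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("rtwmstate")))

  # ---- ingest / simulate ----------------------------------------------------
  sim <- NULL
  pre_records <- NULL
  if (!is.null(cfg$simulate)) {
    sim <- .stage("simulate", {
      sc <- do.call(sim_config, utils::modifyList(list(seed = cfg$seed),
                                                  cfg$simulate))
      simulate_cohort(sc)
    })
    pre_records <- if (cfg$negative_control) simulate_prebaseline(sim) else NULL
    records <- bind_rows(sim$records, pre_records)
    covariates <- sim$covariates
    companies <- sim$companies
    res$truth <- sim$truth
    if (is.null(cfg$inclusion_window)) {
      cfg$inclusion_window <- c(sim$config$inclusion_start,
                                sim$config$inclusion_start +
                                  sim$config$inclusion_span_days)
    }
  } else {
    records <- .stage("ingest", .read_csv_quiet(cfg$records))
    covariates <- .stage("ingest", .read_csv_quiet(cfg$covariates))
    companies <- if (!is.null(cfg$companies)) {
      .stage("ingest", .read_csv_quiet(cfg$companies))
    } else NULL
  }
  if (is.null(cfg$inclusion_window)) cfg$inclusion_window <- c(-Inf, Inf)
  manifest$n_persons_ingested <- dplyr::n_distinct(records$person_id)

  # ---- resolve --------------------------------------------------------------
  episodes <- .stage("resolve", resolve_records(records))
  .write_csv_maybe(episodes, cfg$outdir, "episodes.csv")

  # ---- cohort ---------------------------------------------------------------
  cohort <- .stage("cohort", extract_baseline_cohort(
    episodes, covariates, records = records, companies = companies,
    washout_days = cfg$washout_days, min_sa_days = cfg$min_sa_days,
    inclusion_window = cfg$inclusion_window))
  excl <- attr(cohort, "exclusions")
  manifest$n_no_qualifying_episode <- excl$n[excl$reason == "no_qualifying_episode"]
  manifest$n_excluded_washout <- excl$n[excl$reason == "washout"]
  manifest$n_included <- nrow(cohort)

  # ---- subgroup -------------------------------------------------------------
  if (!is.null(cfg$subgroup)) {
    sg <- cfg$subgroup
    n_before <- nrow(cohort)
    cohort <- .stage("subgroup", {
      out <- cohort
      if (!is.null(sg$sex)) out <- out %>% filter(.data$sex %in% sg$sex)
      if (!is.null(sg$diagnosis_group)) {
        out <- out %>% filter(.data$diagnosis_group %in% sg$diagnosis_group)
      }
      if (!is.null(sg$industry)) {
        out <- out %>% filter(.data$industry %in% sg$industry)
      }
      if (isTRUE(sg$exclude_pregnancy)) {
        out <- out %>% filter(.data$diagnosis_group != "pregnancy_related")
      }
      out
    })
    manifest$n_excluded_subgroup <- n_before - nrow(cohort)
    manifest$n_analysed <- nrow(cohort)
  } else {
    manifest$n_excluded_subgroup <- 0L
    manifest$n_analysed <- nrow(cohort)
  }
  .write_csv_maybe(cohort, cfg$outdir, "cohort.csv")

  # ---- trajectories / counting process -------------------------------------
  trajectories <- .stage("clock_reset", clock_reset_and_truncate(
    episodes, cohort, horizon = cfg$horizon_days,
    death = if ("death_day" %in% names(covariates)) covariates else NULL))
  transitions <- .stage("counting_process", to_counting_process(trajectories))
  .write_csv_maybe(trajectories, cfg$outdir, "trajectories.csv")
  .write_csv_maybe(transitions, cfg$outdir, "transitions.csv")

  # ---- weights --------------------------------------------------------------
  propensity <- .stage("weights", fit_propensity(cohort, cfg$adjustment_set))
  weights <- .stage("weights", stabilized_weights(propensity))
  balance <- .stage("weights", balance_table(cohort, weights))
  .write_csv_maybe(weights, cfg$outdir, "weights.csv")
  .write_csv_maybe(balance, cfg$outdir, "balance.csv")

  # ---- estimation -----------------------------------------------------------
  curves <- .stage("estimate", estimate_arm_curves(
    transitions, cohort, weights, horizon = cfg$horizon_days))
  effect <- .stage("estimate", effect_curve(curves))
  elos_tab <- .stage("estimate", elos(curves, tau = cfg$elos_tau))
  curves_unweighted <- .stage("estimate", estimate_arm_curves(
    transitions, cohort, weights = NULL, horizon = cfg$horizon_days))
  effect_unweighted <- effect_curve(curves_unweighted)
  .write_csv_maybe(curves, cfg$outdir, "curves.csv")
  .write_csv_maybe(effect, cfg$outdir, "effect.csv")
  .write_csv_maybe(effect_unweighted, cfg$outdir, "effect_unweighted.csv")
  if (!is.null(cfg$outdir)) {
    jsonlite::write_json(elos_tab, file.path(cfg$outdir, "elos.json"),
                         dataframe = "rows", digits = NA)
  }

  # ---- bootstrap ------------------------------------------------------------
  boot <- NULL
  if (isTRUE(cfg$bootstrap$enabled)) {
    boot <- .stage("bootstrap", cluster_bootstrap(
      cohort, transitions, adjustment_set = cfg$adjustment_set,
      B = cfg$bootstrap$B %||% 1000,
      seed = cfg$bootstrap$seed %||% cfg$seed,
      horizon = cfg$horizon_days, tau = cfg$elos_tau))
    .write_csv_maybe(boot$theta_bands, cfg$outdir, "effect_bands.csv")
    .write_csv_maybe(boot$elos_bands, cfg$outdir, "elos_bands.csv")
  }

  # ---- negative control -----------------------------------------------------
  negcontrol <- NULL
  if (isTRUE(cfg$negative_control)) {
    pre_traj <- .stage("negative_control", {
      pre <- episodes %>%
        inner_join(cohort %>% select("person_id", "baseline_day"),
                   by = "person_id") %>%
        mutate(start_t = .data$start_day - .data$baseline_day,
               end_t = pmin(.data$end_day - .data$baseline_day, 0)) %>%
        filter(.data$start_t < 0, .data$end_t > .data$start_t) %>%
        select("person_id", "state", "start_t", "end_t")
      pre
    })
    if (nrow(pre_traj)) {
      negcontrol <- .stage("negative_control",
                           negative_control(pre_traj, cohort, weights))
      .write_csv_maybe(negcontrol$curves, cfg$outdir, "negative_control.csv")
    }
  }

  manifest$counts_consistent <-
    manifest$n_persons_ingested == manifest$n_no_qualifying_episode +
    manifest$n_excluded_washout + manifest$n_excluded_subgroup +
    manifest$n_analysed
  if (!is.null(cfg$outdir)) {
    m <- manifest
    m$config <- cfg[c("washout_days", "min_sa_days", "horizon_days",
                      "elos_tau", "adjustment_set", "seed")]
    jsonlite::write_json(m, file.path(cfg$outdir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }

  res <- c(res, list(
    sim = sim, episodes = episodes, cohort = cohort,
    trajectories = trajectories, transitions = transitions,
    propensity = propensity, weights = weights, balance = balance,
    curves = curves, effect = effect, elos = elos_tab,
    curves_unweighted = curves_unweighted,
    effect_unweighted = effect_unweighted,
    bootstrap = boot, negative_control = negcontrol,
    manifest = manifest))
  class(res) <- "rtw_analysis"
  if (is.null(cfg$outdir)) res else invisible(res)
}

#' @export
print.rtw_analysis <- function(x, ...) {
  m <- x$manifest
  cat("Multistate return-to-work analysis\n")
  cat(sprintf("  persons: %d ingested, %d no qualifying episode, %d washout, %d analysed\n",
              m$n_persons_ingested, m$n_no_qualifying_episode,
              m$n_excluded_washout, m$n_analysed))
  peak <- tidy(x$effect) %>%
    filter(.data$state == "WORK") %>%
    slice_max(.data$estimate, n = 1, with_ties = FALSE)
  cat(sprintf("  peak WORK effect: %.4f at day %d\n", peak$estimate, peak$time))
  invisible(x)
}

#' @method glance rtw_analysis
#' @export
glance.rtw_analysis <- function(x, ...) {
  m <- x$manifest
  tibble::tibble(n_ingested = m$n_persons_ingested,
                 n_no_qualifying_episode = m$n_no_qualifying_episode,
                 n_excluded_washout = m$n_excluded_washout,
                 n_excluded_subgroup = m$n_excluded_subgroup,
                 n_analysed = m$n_analysed,
                 seed = m$seed)
}

#' Sensitivity sweep over adjustment sets
#'
#' Re-runs the estimation for several confounder adjustment sets and aligns
#' the resulting effect estimates for comparison. Duplicate sets are
#' deduplicated with a warning. The bootstrap is disabled inside the sweep.
#'
#' @param config As for [run_full_analysis()].
#' @param adjustment_sets A list of character vectors (confounder names);
#'   `character(0)` is the unadjusted analysis.
#' @param eval_times Days at which the WORK effect is reported.
#' @return A tibble with one row per adjustment set: the WORK effect at
#'   `eval_times` and the ELOS differences per state.
#' @export
run_adjustment_sweep <- function(config, adjustment_sets,
                                 eval_times = c(50, 100, 365)) {
  cfg <- if (inherits(config, "rtw_analysis_config")) config else
    analysis_config(config)
  keys <- vapply(adjustment_sets, function(s)
    paste(sort(s), collapse = "+"), character(1))
  if (anyDuplicated(keys)) {
    warn("duplicate adjustment sets supplied; deduplicating")
    adjustment_sets <- adjustment_sets[!duplicated(keys)]
    keys <- keys[!duplicated(keys)]
  }
  cfg$bootstrap <- list(enabled = FALSE)
  cfg$outdir <- NULL
  purrr::map2_dfr(adjustment_sets, keys, function(set, key) {
    cfg$adjustment_set <- set
    run <- run_full_analysis(cfg)
    eff <- tidy(run$effect) %>%
      filter(.data$state == "WORK", .data$time %in% eval_times)
    out <- tibble::tibble(adjustment_set = if (nzchar(key)) key else "(none)")
    for (i in seq_along(eval_times)) {
      out[[paste0("theta_work_", eval_times[i])]] <-
        eff$estimate[eff$time == eval_times[i]]
    }
    el <- run$elos
    for (s in el$state) {
      out[[paste0("elos_diff_", tolower(s))]] <- el$diff[el$state == s]
    }
    out
  })
}
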