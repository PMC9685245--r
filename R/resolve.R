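#' Validate raw registry records
#'
#' Checks the structural invariants of raw registry records: half-open integer
#' day intervals with `end_day > start_day`, a sickness-absence grade present
#' exactly for `sickness_absence` records (in (0, 100]; 100 means full-time),
#' and a company id absent outside `work` records (work records may omit it
#' when the employer is unknown).
#'
#' @param records A data frame with columns `person_id`, `record_type`
#'   (one of `"sickness_absence"`, `"work"`, `"education"`), `start_day`,
#'   `end_day`, and optionally `grade`, `diagnosis_group`, `company_id`.
#' @return The records, invisibly, as a tibble (invalid input aborts).
#' @export
validate_records <- function(records) {
  records <- .as_tbl(records)
  .assert_cols(records, c("person_id", "record_type", "start_day", "end_day"),
               "records")
  if (!"grade" %in% names(records)) records$grade <- NA_real_
  if (!"company_id" %in% names(records)) records$company_id <- NA
  if (!"diagnosis_group" %in% names(records)) records$diagnosis_group <- NA_character_
  bad_type <- setdiff(unique(records$record_type), names(.RECORD_PRECEDENCE))
  if (length(bad_type)) {
    abort(paste0("unknown record_type(s): ", paste(bad_type, collapse = ", ")))
  }
  if (any(records$end_day <= records$start_day)) {
    i <- which(records$end_day <= records$start_day)[1]
    abort(paste0("record intervals must satisfy end_day > start_day; ",
                 "violated for person ", records$person_id[i]))
  }
  is_sa <- records$record_type == "sickness_absence"
  if (any(is_sa & is.na(records$grade))) {
    abort("sickness_absence records must carry a grade")
  }
  if (any(is_sa & (records$grade <= 0 | records$grade > 100))) {
    abort("sickness-absence grades must lie in (0, 100]")
  }
  if (any(!is_sa & !is.na(records$grade))) {
    abort("grade must be present only on sickness_absence records")
  }
  is_work <- records$record_type == "work"
  if (any(!is_work & !is.na(records$company_id))) {
    abort("company_id must be present only on work records")
  }
  invisible(records)
}

# resolve one person's records (plain data frame slice) into episodes.
# Returns a list(state=chr, start=int, end=int) or NULL when nothing covered.
.resolve_one <- function(start, end, type_prec, grade, person_id,
                         window = NULL) {
  if (!is.null(window)) {
    start <- pmax(start, window[1])
    end <- pmin(end, window[2])
    keep <- end > start
    start <- start[keep]; end <- end[keep]
    type_prec <- type_prec[keep]; grade <- grade[keep]
  }
  if (!length(start)) return(NULL)

  lo <- if (is.null(window)) min(start) else window[1]
  hi <- if (is.null(window)) max(end) else window[2]
  pts <- sort(unique(c(start, end, lo, hi)))
  pts <- pts[pts >= lo & pts <= hi]
  a <- pts[-length(pts)]  # elementary interval starts
  b <- pts[-1]            # elementary interval ends
  m <- length(a)
  if (!m) return(NULL)

  # cover[k, i] : record k covers elementary interval i
  cover <- outer(start, a, `<=`) & outer(end, a, `>`)
  prec_mat <- cover * type_prec
  best <- apply(prec_mat, 2L, max)

  # contradictory overlapping sickness-absence grades
  sa_rows <- which(type_prec == .RECORD_PRECEDENCE[["sickness_absence"]])
  if (length(sa_rows) > 1L) {
    for (i in seq_len(m)) {
      g <- unique(grade[sa_rows[cover[sa_rows, i]]])
      if (length(g) > 1L) {
        abort(paste0("overlapping sickness-absence records with ",
                     "contradictory grades for person ", person_id,
                     " on days [", a[i], ", ", b[i], ")"))
      }
    }
  }

  state <- rep(NA_character_, m)
  for (i in seq_len(m)) {
    if (best[i] == 0) next
    if (best[i] == .RECORD_PRECEDENCE[["sickness_absence"]]) {
      g <- grade[sa_rows[cover[sa_rows, i]]][1]
      state[i] <- if (g == 100) "FSA" else "GSA"
    } else if (best[i] == .RECORD_PRECEDENCE[["work"]]) {
      state[i] <- "WORK"
    } else {
      state[i] <- "EDU"
    }
  }

  covered <- which(!is.na(state))
  if (!length(covered)) return(NULL)
  last_cov <- max(covered)
  # gaps with later covered records become non-employment; trailing gap is
  # dropped (right-censoring at the last covered day)
  gap <- is.na(state) & seq_len(m) <= last_cov
  state[gap] <- "NONEMP"
  keep <- seq_len(last_cov)
  state <- state[keep]; a <- a[keep]; b <- b[keep]

  # merge adjacent equal states
  if (length(state) > 1L) {
    new_run <- c(TRUE, state[-1] != state[-length(state)] |
                   a[-1] != b[-length(b)])
    run <- cumsum(new_run)
    a <- a[!duplicated(run)]
    b <- vapply(split(b, run), max, numeric(1), USE.NAMES = FALSE)
    state <- state[new_run]
  }
  list(state = state, start = a, end = b)
}

#' Resolve overlapping registry records into state episodes
#'
#' Turns dated, possibly overlapping registry records into a day-level state
#' episode sequence per person. When several record types cover the same day,
#' precedence is sickness absence, then work, then education. Sickness absence
#' with grade 100 maps to `FSA`, any lower grade to `GSA`. Days not covered by
#' any record are non-employment (`NONEMP`) when later records exist; a
#' trailing uncovered period means loss to follow-up and is dropped, so each
#' person's last episode ends at their right-censoring day. Overlapping
#' sickness-absence records with contradictory grades are rejected.
#'
#' @param records Raw records as in [validate_records()]; may contain many
#'   persons.
#' @param window Optional integer vector `c(start, end)` clipping all records
#'   to a half-open calendar window. Default: each person's own record span.
#' @return A tibble of episodes with columns `person_id`, `state`,
#'   `start_day`, `end_day` (half-open calendar day intervals), ordered by
#'   person and time.
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   person_id = 1, record_type = c("work", "sickness_absence"),
#'   start_day = c(0, 10), end_day = c(100, 40), grade = c(NA, 100)
#' )
#' resolve_records(recs)
resolve_records <- function(records, window = NULL) {
  records <- validate_records(records)
  if (!is.null(window)) {
    stopifnot(is.numeric(window), length(window) == 2L, window[2] > window[1])
  }
  if (!nrow(records)) {
    return(tibble::tibble(person_id = records$person_id[0],
                          state = character(), start_day = integer(),
                          end_day = integer()))
  }
  prec <- .RECORD_PRECEDENCE[records$record_type]
  ord <- order(records$person_id)
  pid <- records$person_id[ord]
  start <- as.numeric(records$start_day[ord])
  end <- as.numeric(records$end_day[ord])
  prec <- unname(prec[ord])
  grade <- records$grade[ord]

  idx <- split(seq_along(pid), pid)
  parts <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    j <- idx[[k]]
    parts[[k]] <- .resolve_one(start[j], end[j], prec[j], grade[j],
                               pid[j[1]], window)
  }
  keep <- !vapply(parts, is.null, logical(1))
  ids <- names(idx)[keep]
  parts <- parts[keep]
  n_ep <- vapply(parts, function(p) length(p$state), integer(1))
  pid_out <- rep(ids, n_ep)
  # restore original person_id type
  proto <- records$person_id
  if (is.numeric(proto)) pid_out <- as.numeric(pid_out)
  tibble::tibble(
    person_id = pid_out,
    state = unlist(lapply(parts, `[[`, "state"), use.names = FALSE),
    start_day = unlist(lapply(parts, `[[`, "start"), use.names = FALSE),
    end_day = unlist(lapply(parts, `[[`, "end"), use.names = FALSE)
  )
}
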