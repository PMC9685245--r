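# Independent day-by-day brute-force oracle for the record resolver, and a
# random record-set generator with forced overlaps.

oracle_resolve_person <- function(recs, window = NULL) {
  start <- pmax(recs$start_day, if (is.null(window)) -Inf else window[1])
  end <- pmin(recs$end_day, if (is.null(window)) Inf else window[2])
  keep <- end > start
  recs <- recs[keep, , drop = FALSE]
  start <- start[keep]; end <- end[keep]
  if (!nrow(recs)) return(NULL)
  lo <- if (is.null(window)) min(start) else window[1]
  hi <- if (is.null(window)) max(end) else window[2]
  days <- lo:(hi - 1)
  state <- rep(NA_character_, length(days))
  prec <- c(sickness_absence = 3L, work = 2L, education = 1L)[recs$record_type]
  for (i in seq_along(days)) {
    d <- days[i]
    cov <- which(start <= d & end > d)
    if (!length(cov)) next
    best <- cov[which.max(prec[cov])]
    if (recs$record_type[best] == "sickness_absence") {
      g <- unique(recs$grade[cov[recs$record_type[cov] == "sickness_absence"]])
      if (length(g) > 1) stop("contradictory grades")
      state[i] <- if (g == 100) "FSA" else "GSA"
    } else if (recs$record_type[best] == "work") {
      state[i] <- "WORK"
    } else {
      state[i] <- "EDU"
    }
  }
  covered <- which(!is.na(state))
  if (!length(covered)) return(NULL)
  last <- max(covered)
  state[seq_len(last)][is.na(state[seq_len(last)])] <- "NONEMP"
  state <- state[seq_len(last)]
  days <- days[seq_len(last)]
  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- c(1, head(ends, -1) + 1)
  tibble::tibble(state = runs$values,
                 start_day = days[starts], end_day = days[ends] + 1)
}

oracle_resolve <- function(records, window = NULL) {
  parts <- lapply(split(records, records$person_id), oracle_resolve_person,
                  window = window)
  parts <- parts[!vapply(parts, is.null, logical(1))]
  out <- dplyr::bind_rows(parts, .id = "person_id")
  out$person_id <- as.numeric(out$person_id)
  dplyr::arrange(out, person_id, start_day)[, c("person_id", "state",
                                                "start_day", "end_day")]
}

# random record sets with forced overlaps; one consistent SA grade per person
# so that overlapping SA records never contradict
random_records <- function(n_persons, max_records = 6, span = 120) {
  per <- lapply(seq_len(n_persons), function(p) {
    k <- sample(1:max_records, 1)
    type <- sample(c("sickness_absence", "work", "education"), k, TRUE)
    start <- sample(0:(span - 2), k, TRUE)
    len <- sample(1:40, k, TRUE)
    g <- sample(c(100, 50), 1)
    out <- tibble::tibble(
      person_id = p, record_type = type, start_day = start,
      end_day = pmin(start + len, span),
      grade = ifelse(type == "sickness_absence", g, NA_real_),
      company_id = ifelse(type == "work", 1L, NA_integer_))
    # force an overlap: a work record spanning the first record
    forced <- tibble::tibble(
      person_id = p, record_type = "work",
      start_day = max(0, out$start_day[1] - 5),
      end_day = out$end_day[1] + 5,
      grade = NA_real_, company_id = 1L)
    dplyr::bind_rows(out, forced)
  })
  dplyr::bind_rows(per)
}

# map resolved episodes back to an equivalent non-overlapping record set
episodes_to_records <- function(episodes) {
  ep <- episodes[episodes$state != "NONEMP", , drop = FALSE]
  tibble::tibble(
    person_id = ep$person_id,
    record_type = c(FSA = "sickness_absence", GSA = "sickness_absence",
                    WORK = "work", EDU = "education")[ep$state],
    start_day = ep$start_day, end_day = ep$end_day,
    grade = dplyr::case_when(ep$state == "FSA" ~ 100,
                             ep$state == "GSA" ~ 50,
                             TRUE ~ NA_real_),
    company_id = ifelse(ep$state == "WORK", 1L, NA_integer_))
}
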