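# internal helpers shared across modules

.assert_cols <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    abort(paste0("`", what, "` is missing required column(s): ",
                 paste(missing, collapse = ", ")))
  }
  invisible(df)
}

.as_tbl <- function(df) tibble::as_tibble(df)

# prepend an S3 class to a tibble without disturbing tibble behaviour
.new_rtw_tbl <- function(df, class, ...) {
  out <- tibble::as_tibble(df)
  attrs <- list(...)
  for (nm in names(attrs)) attr(out, nm) <- attrs[[nm]]
  class(out) <- c(class, class(out))
  out
}

# weighted tabulation of integer day indices onto 1..nbins
.wtab <- function(days, w, nbins) {
  out <- numeric(nbins)
  if (length(days)) {
    keep <- days >= 1L & days <= nbins
    if (any(keep)) {
      s <- rowsum(w[keep], days[keep])
      out[as.integer(rownames(s))] <- s[, 1L]
    }
  }
  out
}

# number of v_i < x for sorted v (strict), vectorised over x
.count_lt <- function(x, v_sorted) findInterval(x, v_sorted, left.open = TRUE)

# merge adjacent equal-state episodes; episodes must be ordered and contiguous
# within person. df has columns person_id, state, start, end (names given).
.merge_adjacent <- function(df, start = "start_day", end = "end_day") {
  if (nrow(df) < 2L) return(df)
  new_run <- df$person_id != lag(df$person_id, default = df$person_id[1]) |
    df$state != lag(df$state, default = paste0(df$state[1], "&")) |
    df[[start]] != lag(df[[end]], default = df[[start]][1])
  new_run[1] <- TRUE
  run <- cumsum(new_run)
  out <- df[!duplicated(run), , drop = FALSE]
  out[[end]] <- df[[end]][c(which(new_run)[-1] - 1L, nrow(df))]
  out
}

# deterministic sub-seed for replicate streams; keeps values < 2^31
.substream_seed <- function(seed, r) {
  as.integer((as.numeric(seed) * 48271 + r * 69621) %% 2147483647)
}

.is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
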