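# State space of the work-life multistate model.
#
# Five transient states (full-time sickness absence, graded sickness absence,
# work, non-employment, education) plus absorbing death. All transitions
# between transient states are allowed and death competes from every state.

.RTW_STATES <- c("FSA", "GSA", "WORK", "NONEMP", "EDU", "DEATH")
.RTW_TRANSIENT <- .RTW_STATES[1:5]
.CENSORED <- "CENSORED"

# record-type precedence used by the resolver: higher wins on a day
.RECORD_PRECEDENCE <- c(sickness_absence = 3L, work = 2L, education = 1L)

#' State space of the multistate model
#'
#' Returns the six states used throughout the package, in canonical order:
#' `FSA` (full-time sickness absence), `GSA` (graded sickness absence),
#' `WORK`, `NONEMP` (non-employment), `EDU` (education) and the absorbing
#' state `DEATH`.
#'
#' @param transient_only If `TRUE`, drop the absorbing `DEATH` state.
#' @return A character vector of state labels.
#' @export
#' @examples
#' rtw_states()
rtw_states <- function(transient_only = FALSE) {
  if (transient_only) .RTW_TRANSIENT else .RTW_STATES
}

.state_index <- function(state, states = .RTW_STATES) {
  i <- match(state, states)
  if (anyNA(i)) {
    abort(paste0("unknown state label(s): ",
                 paste(unique(state[is.na(i)]), collapse = ", ")))
  }
  i
}
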