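# Planning-efficiency timing: named event timestamps with two derived
# endpoints. TTE (time to execute) = plan-creation trigger minus application
# start: the time spent reviewing before committing to automation. TPT
# (technical planning time) = planning end minus planning start: the active
# plan-construction time. All timestamps are injected.

#' Create an empty timing log
#' @return A `timing_log` (zero-row tibble `event`, `time`).
#' @export
timing_log <- function() {
  structure(tibble::tibble(event = character(), time = as.POSIXct(character())),
            class = c("timing_log", "tbl_df", "tbl", "data.frame"))
}

#' Record a named timing event
#'
#' Events must arrive in chronological order (monotone timestamps).
#'
#' @param log A `timing_log`.
#' @param event Event name; the derived endpoints use `"application_start"`,
#'   `"plan_trigger"`, `"planning_start"`, `"planning_end"`.
#' @param time `POSIXct` timestamp (injected clock).
#' @return The updated `timing_log`.
#' @export
log_event <- function(log, event, time) {
  stopifnot(inherits(log, "timing_log"))
  time <- as.POSIXct(time, tz = "UTC")
  if (nrow(log) > 0 && time < log$time[nrow(log)]) {
    stop(sprintf("event '%s' is earlier than the previous event", event), call. = FALSE)
  }
  out <- dplyr::bind_rows(log, tibble::tibble(event = event, time = time))
  structure(out, class = class(log))
}

#' Derived timing endpoints
#'
#' @param log A `timing_log` containing the four standard events.
#' @return List with `tte_s` (application_start to plan_trigger, seconds),
#'   `tpt_s` (planning_start to planning_end), `review_lag_s` (plan_trigger
#'   to planning_start), and `total_s` (plan_trigger to planning_end =
#'   `review_lag_s + tpt_s`).
#' @export
timing_summary <- function(log) {
  stopifnot(inherits(log, "timing_log"))
  at <- function(ev) {
    t <- log$time[log$event == ev]
    if (length(t) == 0) return(NA)
    t[1]
  }
  secs <- function(a, b) as.numeric(difftime(b, a, units = "secs"))
  tte <- secs(at("application_start"), at("plan_trigger"))
  tpt <- secs(at("planning_start"), at("planning_end"))
  lag <- secs(at("plan_trigger"), at("planning_start"))
  list(tte_s = tte, tpt_s = tpt, review_lag_s = lag,
       total_s = if (is.na(lag) || is.na(tpt)) NA_real_ else lag + tpt)
}
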