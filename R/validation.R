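# Planning integrity checks with pass / warning / flag / tracked states and
# a parameter-change audit log. Every check is pure given its inputs: the
# clock is always injected, never read from the wall.

VALIDATION_STATES <- c("pass", "tracked", "warning", "flag") # severity order

validation_result <- function(check_id, state, message = "", timestamp = NA) {
  stopifnot(state %in% VALIDATION_STATES)
  if (state != "pass" && !nzchar(message)) {
    stop("non-pass validation results must carry a message", call. = FALSE)
  }
  tibble::tibble(check_id = check_id, state = state, message = message,
                 timestamp = as.character(timestamp))
}

#' Case context for planning validations
#'
#' @param structure_set_id Structure set label.
#' @param modality Image series modality text (e.g. `"CT"`); may be `NA`.
#' @param acquisition_date Image acquisition date (`Date` or `"YYYY-MM-DD"`).
#' @param referencing_plans Character vector of plan ids already using the
#'   structure set.
#' @param protocol Optional `clinical_protocol`.
#' @return A `case_context`.
#' @export
case_context <- function(structure_set_id, modality = "CT",
                         acquisition_date = NA, referencing_plans = character(),
                         protocol = NULL) {
  structure(
    list(
      structure_set_id = as.character(structure_set_id),
      modality = modality,
      acquisition_date = if (is.na(acquisition_date[1])) NA else as.Date(acquisition_date),
      referencing_plans = as.character(referencing_plans),
      protocol = protocol
    ),
    class = "case_context"
  )
}

#' Warn when the structure set is used by other plans
#'
#' An already-referenced structure set can indicate stale contours from a
#' prior course: warning when any referencing plan exists, pass otherwise.
#'
#' @param ctx A `case_context`.
#' @return One-row validation tibble (`check_id`, `state`, `message`,
#'   `timestamp`).
#' @export
check_other_plans <- function(ctx) {
  stopifnot(inherits(ctx, "case_context"))
  if (length(ctx$referencing_plans) == 0) {
    validation_result("other_plans", "pass")
  } else {
    validation_result("other_plans", "warning",
                      sprintf("structure set '%s' already used by plan(s): %s",
                              ctx$structure_set_id,
                              paste(ctx$referencing_plans, collapse = ", ")))
  }
}

#' Flag planning images older than a threshold
#'
#' Flags when the image is strictly more than `threshold_days` whole calendar
#' days old at `today`; exactly `threshold_days` passes. A future-dated image
#' flags with a distinct message.
#'
#' @param ctx A `case_context` with an acquisition date.
#' @param today Evaluation date (`Date` or `"YYYY-MM-DD"`); injected, never
#'   read from the system clock.
#' @param threshold_days Age threshold in whole days (default 14).
#' @return One-row validation tibble.
#' @export
check_image_age <- function(ctx, today, threshold_days = 14) {
  stopifnot(inherits(ctx, "case_context"))
  today <- as.Date(today)
  if (is.na(ctx$acquisition_date[1])) {
    return(validation_result("image_age", "flag", "image has no acquisition date"))
  }
  age <- as.integer(today - ctx$acquisition_date)
  if (age < 0) {
    validation_result("image_age", "flag",
                      sprintf("image acquisition date %s lies in the future",
                              format(ctx$acquisition_date)))
  } else if (age > threshold_days) {
    validation_result("image_age", "flag",
                      sprintf("image is %d days old (> %d)", age, threshold_days))
  } else {
    validation_result("image_age", "pass")
  }
}

#' Check that the planning image is a CT
#'
#' @param ctx A `case_context`.
#' @return One-row validation tibble; flag unless modality is `"CT"`.
#' @export
check_image_modality <- function(ctx) {
  stopifnot(inherits(ctx, "case_context"))
  mod <- ctx$modality
  if (length(mod) == 1 && !is.na(mod) && identical(toupper(mod), "CT")) {
    validation_result("image_modality", "pass")
  } else {
    validation_result("image_modality", "flag",
                      sprintf("planning image modality is '%s', expected CT",
                              if (length(mod) == 0 || is.na(mod)) "<missing>" else mod))
  }
}

#' Check that the clinical protocol yields a creatable plan
#'
#' Passes iff the protocol parsed, defines at least one field and a
#' prescription, and its target name resolves among the available structures.
#'
#' @param protocol A `clinical_protocol`, or `NULL`/an error condition when
#'   parsing failed.
#' @param available Character vector of structure ids in the case.
#' @param dictionary A `structure_dictionary` used for target resolution.
#' @return One-row validation tibble.
#' @export
check_protocol_interpretation <- function(protocol, available,
                                          dictionary = empty_dictionary()) {
  if (is.null(protocol) || inherits(protocol, "condition")) {
    msg <- if (inherits(protocol, "condition")) conditionMessage(protocol)
           else "protocol failed to parse"
    return(validation_result("protocol_interpretation", "flag", msg))
  }
  stopifnot(inherits(protocol, "clinical_protocol"))
  if (nrow(protocol$fields) == 0) {
    return(validation_result("protocol_interpretation", "flag",
                             "protocol defines no fields"))
  }
  m <- tryCatch(
    match_structure(protocol$prescription$target_id, available, dictionary),
    error = function(e) tibble::tibble(flagged = TRUE, matched = NA_character_)
  )
  if (m$flagged) {
    validation_result("protocol_interpretation", "flag",
                      sprintf("protocol target '%s' not found among planning structures",
                              protocol$prescription$target_id))
  } else {
    validation_result("protocol_interpretation", "pass")
  }
}

#' An empty parameter-change log
#' @return Zero-row tibble with columns `parameter`, `template_value`,
#'   `user_value`, `timestamp`.
#' @export
new_change_log <- function() {
  tibble::tibble(parameter = character(), template_value = character(),
                 user_value = character(), timestamp = character())
}

#' Record a user override of a template parameter
#'
#' Appends a change record iff the user value differs from the template
#' value; identical repeat calls are idempotent (one record per distinct
#' parameter/value pair).
#'
#' @param name Parameter name.
#' @param template_value,user_value Values as text.
#' @param log A change log from [new_change_log()].
#' @param timestamp Optional ISO-8601 text timestamp (injected clock).
#' @return The updated change log.
#' @export
track_parameter <- function(name, template_value, user_value, log = new_change_log(),
                            timestamp = NA_character_) {
  template_value <- as.character(template_value)
  user_value <- as.character(user_value)
  if (identical(template_value, user_value)) return(log)
  dup <- log$parameter == name & log$template_value == template_value &
    log$user_value == user_value
  if (any(dup)) return(log)
  dplyr::bind_rows(log, tibble::tibble(
    parameter = name, template_value = template_value,
    user_value = user_value, timestamp = timestamp
  ))
}

#' Evaluate clinical goals against computed metrics
#'
#' One validation result per goal: pass iff the comparator is satisfied by
#' the evaluated metric value; a goal whose metric was not evaluated flags.
#'
#' @param goals Goal tibble (`structure_id`, `metric`, `comparator`,
#'   `threshold`, `units`), as parsed from a protocol.
#' @param metrics Metric results from [evaluate_metrics()] (`structure_id`,
#'   `metric`, `value`).
#' @return Validation tibble, one row per goal.
#' @export
check_clinical_goals <- function(goals, metrics) {
  purrr::map_dfr(seq_len(nrow(goals)), function(i) {
    g <- goals[i, ]
    hit <- metrics[metrics$structure_id == g$structure_id &
                     metrics$metric == g$metric, ]
    check_id <- sprintf("goal:%s:%s", g$structure_id, g$metric)
    if (nrow(hit) == 0 || is.na(hit$value[1])) {
      return(validation_result(check_id, "flag",
                               sprintf("%s %s not evaluated", g$structure_id, g$metric)))
    }
    v <- hit$value[1]
    ok <- if (g$comparator == "le") v <= g$threshold else v >= g$threshold
    if (ok) {
      validation_result(check_id, "pass")
    } else {
      validation_result(check_id, "flag",
                        sprintf("%s %s = %.2f %s violates goal %s %.2f",
                                g$structure_id, g$metric, v, g$units,
                                if (g$comparator == "le") "<=" else ">=", g$threshold))
    }
  })
}

#' Aggregate validation results into a report
#'
#' @param results Validation tibble (possibly empty) of stacked check rows.
#' @param changes Change log from [track_parameter()].
#' @return A `validation_report`: list with `overall` (worst state present,
#'   ordering pass < tracked < warning < flag; `"pass"` when empty),
#'   `counts` (named integer by state), `results`, `changes`.
#' @export
validation_report <- function(results = NULL, changes = new_change_log()) {
  if (is.null(results)) {
    results <- tibble::tibble(check_id = character(), state = character(),
                              message = character(), timestamp = character())
  }
  counts <- vapply(VALIDATION_STATES, function(s) sum(results$state == s), integer(1))
  overall <- if (nrow(results) == 0) "pass" else {
    VALIDATION_STATES[max(match(results$state, VALIDATION_STATES))]
  }
  if (nrow(changes) > 0 && overall == "pass") overall <- "tracked"
  structure(
    list(overall = overall, counts = counts, results = results, changes = changes),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> overall %s: %s; %d tracked change(s)\n",
              toupper(x$overall),
              paste(sprintf("%d %s", x$counts, names(x$counts)), collapse = ", "),
              nrow(x$changes)))
  invisible(x)
}

#' Write a validation report as JSON
#'
#' @param report A `validation_report`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(report, path) {
  stopifnot(inherits(report, "validation_report"))
  jsonlite::write_json(
    list(
      overall = report$overall,
      counts = as.list(report$counts),
      results = report$results,
      changes = report$changes
    ),
    path, auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(path)
}
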