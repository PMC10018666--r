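# End-to-end automated planning pipeline: the "single click" as a single
# call. Orchestrates case loading, integrity checks, template interpretation,
# derived-structure building, model matching, plan layout, optional dose
# evaluation, and report writing. All randomness flows from the manifest
# seed; all clock reads from the injected clock.

#' Assemble a pipeline run manifest
#'
#' @param case_dir Case directory ([write_case()] format).
#' @param protocol_path Clinical-protocol XML path.
#' @param config_path Automation-config YAML path.
#' @param dictionary_path Structure-dictionary XML path (optional).
#' @param out_dir Output directory.
#' @param dose_engine `"case"` (use `dose.csv` from the case if present),
#'   `"synthetic"` (run the packaged dose emulator), or `"none"`.
#' @param machine Optional machine-id override (tracked as a change).
#' @param fractions Optional fraction-count override (tracked).
#' @param match_overrides Named character vector: planning id -> structure id
#'   chosen by the user (each tracked as a change).
#' @param seed Integer seed driving every stochastic component.
#' @param today Injected evaluation date for age checks (`"YYYY-MM-DD"`).
#' @param clock Injected clock: a function returning `POSIXct`.
#' @return A `run_manifest`. All referenced files must exist.
#' @export
run_manifest <- function(case_dir, protocol_path, config_path,
                         dictionary_path = NULL, out_dir,
                         dose_engine = c("case", "synthetic", "none"),
                         machine = NULL, fractions = NULL,
                         match_overrides = character(), seed = 1,
                         today = Sys.Date(), clock = Sys.time) {
  dose_engine <- match.arg(dose_engine)
  for (p in c(case_dir, protocol_path, config_path, dictionary_path)) {
    if (!is.null(p) && !file.exists(p)) {
      stop(sprintf("manifest references missing input '%s'", p), call. = FALSE)
    }
  }
  structure(
    list(case_dir = case_dir, protocol_path = protocol_path,
         config_path = config_path, dictionary_path = dictionary_path,
         out_dir = out_dir, dose_engine = dose_engine, machine = machine,
         fractions = fractions, match_overrides = match_overrides,
         seed = as.integer(seed), today = as.Date(today), clock = clock),
    class = "run_manifest"
  )
}

append_event <- function(events, clock, message) {
  c(events, sprintf("%s %s", format(clock(), "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC"), message))
}

#' Run the automated planning pipeline
#'
#' Executes, in order: case load; structure-set and image validations;
#' protocol, config and dictionary parsing; derived-structure building
#' (flag-and-continue); model-structure matching with user overrides tracked
#' as changes; isocenter placement, field instantiation and jaw fitting;
#' optional dose evaluation (prescription normalization, goal metrics, goal
#' checks); and artifact writing. Flags and warnings never abort — they are
#' reported; hard errors (missing inputs, unreadable files) raise before any
#' output is written.
#'
#' Artifacts under `out_dir`: `rtstruct_derived.json` (derived-structure
#' contours), `rtplan_skeleton.json`, `validation_report.json`,
#' `metrics.csv`, `dvh.csv`, `timing.json`, `events.log`.
#'
#' @param manifest A [run_manifest()].
#' @return List with `status` (0 on success), `validation`
#'   (`validation_report`), `build_report`, `matches`, `layout`, `metrics`
#'   (tibble or NULL), `goal_results`, `timing` (list), `artifacts`
#'   (character paths).
#' @export
run_pipeline <- function(manifest) {
  stopifnot(inherits(manifest, "run_manifest"))
  clock <- manifest$clock
  tlog <- timing_log()
  tlog <- log_event(tlog, "application_start", clock())
  events <- character()
  events <- append_event(events, clock, "pipeline start")

  # -- load everything up front: hard errors must precede any output --------
  case <- read_case(manifest$case_dir)
  protocol <- parse_clinical_protocol(manifest$protocol_path)
  config <- parse_automation_config(manifest$config_path)
  dictionary <- if (is.null(manifest$dictionary_path)) empty_dictionary()
                else read_structure_dictionary(manifest$dictionary_path)
  events <- append_event(events, clock, sprintf("loaded case '%s' and templates", case$case_id))

  ctx <- case_context(case$structure_set_id, modality = case$modality,
                      acquisition_date = case$acquisition_date,
                      referencing_plans = case$referencing_plans,
                      protocol = protocol)
  changes <- new_change_log()
  now_iso <- function() format(clock(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")

  results <- dplyr::bind_rows(
    check_other_plans(ctx),
    check_image_age(ctx, today = manifest$today),
    check_image_modality(ctx),
    check_protocol_interpretation(protocol, names(case$masks), dictionary)
  )
  events <- append_event(events, clock, "structure-set and image validations done")

  # user overrides are tracked, never silent
  effective_fractions <- protocol$prescription$fractions
  if (!is.null(manifest$fractions) &&
      manifest$fractions != protocol$prescription$fractions) {
    changes <- track_parameter("fractions", protocol$prescription$fractions,
                               manifest$fractions, changes, timestamp = now_iso())
    effective_fractions <- manifest$fractions
  }

  tlog <- log_event(tlog, "plan_trigger", clock())
  tlog <- log_event(tlog, "planning_start", clock())

  built <- build_derived_structures(config$derivation_rules, case$masks, dictionary)
  prv_state <- if (any(built$report$outcome == "flagged")) "flag" else "pass"
  results <- dplyr::bind_rows(results, tibble::tibble(
    check_id = "prv_generation", state = prv_state,
    message = if (prv_state == "pass") "" else sprintf(
      "derivation flagged for: %s",
      paste(built$report$output_id[built$report$outcome == "flagged"], collapse = ", ")),
    timestamp = now_iso()
  ))
  events <- append_event(events, clock, sprintf(
    "derived %d structure(s), %d flagged",
    sum(built$report$outcome == "built"), sum(built$report$outcome == "flagged")))

  matches <- resolve_model_matches(config, names(built$masks), dictionary)
  for (nm in names(manifest$match_overrides)) {
    i <- which(matches$planning_id == nm)
    if (length(i) == 1) {
      prev <- if (is.na(matches$matched[i])) "<none>" else matches$matched[i]
      changes <- track_parameter(paste0("match:", nm), prev,
                                 manifest$match_overrides[[nm]], changes,
                                 timestamp = now_iso())
      matches$matched[i] <- manifest$match_overrides[[nm]]
      matches$tier[i] <- "override"
      matches$flagged[i] <- FALSE
    }
  }

  target_match <- match_structure(protocol$prescription$target_id,
                                  names(built$masks), dictionary)
  if (target_match$flagged) {
    stop(sprintf("protocol target '%s' cannot be resolved; no plan to create",
                 protocol$prescription$target_id), call. = FALSE)
  }
  target <- built$masks[[target_match$matched]]

  isocenter <- place_isocenter(target)
  layout <- build_fields(protocol, isocenter, machine_id = manifest$machine,
                         plan_id = paste0(case$case_id, "_auto"))
  changes <- dplyr::bind_rows(changes, layout$changes)
  layout <- fit_all_jaws(layout, target)
  events <- append_event(events, clock, sprintf(
    "plan layout: %d field(s), isocenter (%.1f, %.1f, %.1f) mm",
    nrow(layout$fields), isocenter[1], isocenter[2], isocenter[3]))

  # -- dose evaluation ------------------------------------------------------
  metrics <- NULL
  goal_results <- NULL
  dvh_tables <- NULL
  rx <- protocol$prescription$total_gy
  dose <- switch(manifest$dose_engine,
    none = NULL,
    case = case$dose,
    synthetic = generate_dose(built$masks, dose_model_spec(seed = manifest$seed))
  )
  if (!is.null(dose)) {
    norm <- normalize_prescription(dose, target, rx)
    metrics <- evaluate_metrics(norm$dose, built$masks, protocol$goals, rx = rx,
                                target_id = protocol$prescription$target_id,
                                dictionary = dictionary,
                                bilateral_map = config$bilateral_map)
    goal_results <- check_clinical_goals(protocol$goals, metrics)
    results <- dplyr::bind_rows(results, goal_results)
    eval_ids <- unique(c(protocol$goals$structure_id, protocol$prescription$target_id))
    dvh_tables <- purrr::map_dfr(eval_ids, function(id) {
      msk <- if (id %in% names(config$bilateral_map)) {
        comp <- config$bilateral_map[[id]]
        present <- intersect(comp, names(built$masks))
        if (length(present) == 0) return(NULL)
        boolean_combine(built$masks[present], "union", structure_id = id)
      } else if (id %in% names(built$masks)) built$masks[[id]] else NULL
      if (is.null(msk) || !any(msk$occupancy)) return(NULL)
      tidy(compute_dvh(norm$dose, msk), bin_gy = 0.25)
    })
    events <- append_event(events, clock, sprintf(
      "dose evaluated: normalization x%.4f, %d metric(s)", norm$scale, nrow(metrics)))
  }

  tlog <- log_event(tlog, "planning_end", clock())
  report <- validation_report(results, changes)

  # -- artifacts ------------------------------------------------------------
  dir.create(manifest$out_dir, showWarnings = FALSE, recursive = TRUE)
  derived_ids <- built$report$output_id[built$report$outcome == "built"]
  art <- character()
  rtstruct_path <- file.path(manifest$out_dir, "rtstruct_derived.json")
  jsonlite::write_json(
    lapply(derived_ids, function(id) contours_to_list(mask_to_contours(built$masks[[id]]))),
    rtstruct_path, auto_unbox = TRUE, digits = NA)
  art <- c(art, rtstruct_path)

  rtplan_path <- file.path(manifest$out_dir, "rtplan_skeleton.json")
  jsonlite::write_json(layout_to_list(layout), rtplan_path,
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  art <- c(art, rtplan_path)

  report_path <- file.path(manifest$out_dir, "validation_report.json")
  write_validation_report(report, report_path)
  art <- c(art, report_path)

  if (!is.null(metrics)) {
    metrics_path <- file.path(manifest$out_dir, "metrics.csv")
    utils::write.csv(dplyr::mutate(metrics, case_id = case$case_id),
                     metrics_path, row.names = FALSE)
    art <- c(art, metrics_path)
    dvh_path <- file.path(manifest$out_dir, "dvh.csv")
    utils::write.csv(dvh_tables, dvh_path, row.names = FALSE)
    art <- c(art, dvh_path)
  }

  timing <- timing_summary(tlog)
  timing_path <- file.path(manifest$out_dir, "timing.json")
  jsonlite::write_json(timing, timing_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  art <- c(art, timing_path)

  events <- append_event(events, clock, "pipeline end")
  events_path <- file.path(manifest$out_dir, "events.log")
  writeLines(events, events_path)
  art <- c(art, events_path)

  list(status = 0L, validation = report, build_report = built$report,
       matches = matches, layout = layout, metrics = metrics,
       goal_results = goal_results, timing = timing, artifacts = art,
       masks = built$masks)
}
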