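# Metric specification parsing and goal-driven metric evaluation.
#
# Metric grammar (as printed in clinical goal sheets):
#   "D2%"      dose covering the hottest 2% of the volume      -> Gy
#   "D0.03cc"  dose covering the hottest 0.03 cm^3             -> Gy
#   "V30Gy"    volume receiving at least 30 Gy                 -> %
#   "Dmin" / "Dmax"                                            -> Gy
#   "HI"       homogeneity index at the prescription            -> %

#' Parse a metric label
#'
#' @param label Metric text such as `"D2%"`, `"D0.03cc"`, `"V30Gy"`,
#'   `"Dmin"`, `"Dmax"`, `"HI"`.
#' @return A `metric_spec`: list with `kind` (`D_percent`, `D_cc`, `V_gy`,
#'   `D_min`, `D_max`, `HI`), `argument` (numeric or NA) and `units` of the
#'   result.
#' @export
parse_metric <- function(label) {
  lab <- gsub(" ", "", label)
  spec <- if (toupper(lab) == "HI") {
    list(kind = "HI", argument = NA_real_, units = "%")
  } else if (toupper(lab) == "DMIN") {
    list(kind = "D_min", argument = NA_real_, units = "Gy")
  } else if (toupper(lab) == "DMAX") {
    list(kind = "D_max", argument = NA_real_, units = "Gy")
  } else if (grepl("^D[0-9.]+%$", lab)) {
    arg <- as.numeric(sub("^D([0-9.]+)%$", "\\1", lab))
    if (arg <= 0 || arg > 100) stop(sprintf("D%% argument out of (0, 100]: '%s'", label), call. = FALSE)
    list(kind = "D_percent", argument = arg, units = "Gy")
  } else if (grepl("^D[0-9.]+cc$", lab, ignore.case = TRUE)) {
    arg <- as.numeric(sub("^D([0-9.]+)cc$", "\\1", lab, ignore.case = TRUE))
    if (arg <= 0) stop(sprintf("Dcc argument must be > 0: '%s'", label), call. = FALSE)
    list(kind = "D_cc", argument = arg, units = "Gy")
  } else if (grepl("^V[0-9.]+Gy$", lab, ignore.case = TRUE)) {
    arg <- as.numeric(sub("^V([0-9.]+)Gy$", "\\1", lab, ignore.case = TRUE))
    if (arg <= 0) stop(sprintf("VGy argument must be > 0: '%s'", label), call. = FALSE)
    list(kind = "V_gy", argument = arg, units = "%")
  } else {
    stop(sprintf("unrecognized metric label '%s'", label), call. = FALSE)
  }
  structure(c(spec, list(label = label)), class = "metric_spec")
}

# evaluate one parsed metric on a DVH
eval_metric_spec <- function(spec, dvh, rx = NULL) {
  switch(
    spec$kind,
    D_percent = dose_at_volume(dvh, percent = spec$argument),
    D_cc = dose_at_volume(dvh, cc = spec$argument),
    V_gy = volume_at_dose(dvh, spec$argument),
    D_min = min(dvh$samples),
    D_max = max(dvh$samples),
    HI = {
      if (is.null(rx)) stop("HI requires a prescription dose", call. = FALSE)
      homogeneity_index(dvh, rx)
    }
  )
}

#' Evaluate clinical-goal metrics on a dose distribution
#'
#' One metric result per goal, plus the homogeneity index of the target when
#' `rx` is given. Goal structure names are resolved through
#' [match_structure()]; a `bilateral_map` entry (e.g. `OpticNerves =
#' c("OpticNerve_L", "OpticNerve_R")`) evaluates the goal on the union of the
#' component masks, the way bilateral organs are reported clinically. A goal
#' whose structure cannot be resolved yields an `NA` value flagged for
#' [check_clinical_goals()].
#'
#' @param dose A `dose_grid`.
#' @param masks Named list of `structure_mask` objects on the dose grid.
#' @param goals Goal tibble (`structure_id`, `metric`, `comparator`,
#'   `threshold`, `units`).
#' @param rx Prescription dose in Gy; enables the HI row for `target_id`.
#' @param target_id Target structure id for the HI row.
#' @param dictionary A `structure_dictionary`.
#' @param bilateral_map Named list of component structure ids.
#' @return Tibble: `structure_id`, `metric`, `value`, `units`, `resolved`
#'   (actual mask(s) used), `flagged`.
#' @export
evaluate_metrics <- function(dose, masks, goals, rx = NULL, target_id = NULL,
                             dictionary = empty_dictionary(),
                             bilateral_map = list()) {
  stopifnot(inherits(dose, "dose_grid"), is.list(masks))
  resolve_eval_mask <- function(structure_id) {
    if (structure_id %in% names(bilateral_map)) {
      comp <- bilateral_map[[structure_id]]
      found <- lapply(comp, function(id) {
        m <- match_structure(id, names(masks), dictionary)
        if (m$flagged) NULL else masks[[m$matched]]
      })
      found <- Filter(Negate(is.null), found)
      if (length(found) == 0) return(NULL)
      return(boolean_combine(found, "union", structure_id = structure_id))
    }
    m <- match_structure(structure_id, names(masks), dictionary)
    if (m$flagged) NULL else masks[[m$matched]]
  }

  dvh_cache <- list()
  get_dvh <- function(structure_id) {
    if (!is.null(dvh_cache[[structure_id]])) return(dvh_cache[[structure_id]])
    msk <- resolve_eval_mask(structure_id)
    if (is.null(msk) || !any(msk$occupancy)) return(NULL)
    d <- compute_dvh(dose, msk)
    dvh_cache[[structure_id]] <<- d
    d
  }

  rows <- purrr::map_dfr(seq_len(nrow(goals)), function(i) {
    g <- goals[i, ]
    dvh <- get_dvh(g$structure_id)
    if (is.null(dvh)) {
      return(tibble::tibble(structure_id = g$structure_id, metric = g$metric,
                            value = NA_real_, units = g$units,
                            resolved = NA_character_, flagged = TRUE))
    }
    spec <- parse_metric(g$metric)
    tibble::tibble(
      structure_id = g$structure_id, metric = g$metric,
      value = eval_metric_spec(spec, dvh, rx = rx),
      units = spec$units, resolved = dvh$structure_id, flagged = FALSE
    )
  })

  if (!is.null(rx) && !is.null(target_id)) {
    dvh <- get_dvh(target_id)
    hi_row <- if (is.null(dvh)) {
      tibble::tibble(structure_id = target_id, metric = "HI", value = NA_real_,
                     units = "%", resolved = NA_character_, flagged = TRUE)
    } else {
      tibble::tibble(structure_id = target_id, metric = "HI",
                     value = homogeneity_index(dvh, rx), units = "%",
                     resolved = dvh$structure_id, flagged = FALSE)
    }
    rows <- dplyr::bind_rows(rows, hi_row)
  }
  rows
}
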