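# Derived-structure builder: executes declarative rules (Boolean algebra,
# margins, rings, half-space crops) against a structure set, flag-and-continue
# on missing operands.

# resolve one operand name: "$k" references a prior step result
resolve_operand <- function(name, step_results, masks, dictionary) {
  if (grepl("^\\$[0-9]+$", name)) {
    k <- as.integer(sub("\\$", "", name))
    if (k < 1 || k > length(step_results) || is.null(step_results[[k]])) {
      stop(sprintf("step reference '%s' points to a step that has not run", name),
           call. = FALSE)
    }
    return(list(mask = step_results[[k]], missing = NULL))
  }
  m <- match_structure(name, names(masks), dictionary)
  if (m$flagged) return(list(mask = NULL, missing = name))
  list(mask = masks[[m$matched]], missing = NULL)
}

# crop an operand to an axis-aligned sub-box of a reference bounding box.
# anterior_frac keeps y < ymin + frac * (ymax - ymin) (anterior = small y in
# LPS); inferior_frac keeps z < zmin + frac * (zmax - zmin).
crop_to_region <- function(mask, ref, anterior_frac = NULL, inferior_frac = NULL) {
  bb <- mask_bbox(ref)
  if (is.null(bb)) return(empty_mask(mask$grid, mask$structure_id))
  g <- mask$grid
  ax <- axis_centers(g)
  keep <- array(TRUE, g$dims)
  if (!is.null(anterior_frac)) {
    ycut <- bb$min[2] + anterior_frac * (bb$max[2] - bb$min[2])
    keep <- keep & aperm(array(rep(ax[[2]] < ycut, each = g$dims[1]),
                               dim = c(g$dims[1], g$dims[2], g$dims[3])), c(1, 2, 3))
  }
  if (!is.null(inferior_frac)) {
    zcut <- bb$min[3] + inferior_frac * (bb$max[3] - bb$min[3])
    kz <- ax[[3]] < zcut
    keep <- keep & array(rep(kz, each = g$dims[1] * g$dims[2]), dim = g$dims)
  }
  structure_mask(g, mask$occupancy & keep, mask$structure_id)
}

execute_rule <- function(rule, masks, dictionary) {
  step_results <- vector("list", length(rule$steps))
  for (si in seq_along(rule$steps)) {
    s <- rule$steps[[si]]
    ops <- lapply(s$operands, resolve_operand, step_results = step_results,
                  masks = masks, dictionary = dictionary)
    missing <- unlist(lapply(ops, function(o) o$missing))
    if (length(missing) > 0) {
      return(list(mask = NULL, missing = missing))
    }
    opmasks <- lapply(ops, function(o) o$mask)
    g <- opmasks[[1]]$grid
    for (m in opmasks[-1]) {
      if (!grid_equal(g, m$grid)) stop("derivation operands lie on different grids", call. = FALSE)
    }
    step_results[[si]] <- switch(
      s$verb,
      union = ,
      intersection = ,
      subtraction = ,
      xor = boolean_combine(opmasks, s$verb, structure_id = rule$output_id),
      margin = {
        if (length(opmasks) != 1) stop("margin takes exactly one operand", call. = FALSE)
        expand_margin(opmasks[[1]], s$mm)
      },
      ring = {
        if (length(opmasks) != 1) stop("ring takes exactly one operand", call. = FALSE)
        ring(opmasks[[1]], s$inner_mm %||% 0, s$outer_mm)
      },
      crop_to = {
        if (length(opmasks) != 2) stop("crop_to takes operands (structure, reference)", call. = FALSE)
        crop_to_region(opmasks[[1]], opmasks[[2]],
                       anterior_frac = s$anterior_frac, inferior_frac = s$inferior_frac)
      }
    )
  }
  out <- step_results[[length(step_results)]]
  out$structure_id <- rule$output_id
  list(mask = out, missing = NULL)
}

#' Execute derivation rules against a structure set
#'
#' Rules run in order; later rules may consume earlier outputs. Operand names
#' are resolved through [match_structure()]. A rule with any unresolved
#' operand is flagged and skipped; the remaining rules still run. Input masks
#' are never modified.
#'
#' @param rules List of [derivation_rule()] objects.
#' @param masks Named list of `structure_mask` objects on a common grid.
#' @param dictionary A `structure_dictionary` for operand name resolution.
#' @return List with `masks` (the input masks plus derived ones) and `report`
#'   (`build_report` tibble: `output_id`, `outcome` `"built"`/`"flagged"`,
#'   `missing` comma-joined missing operand names, `volume_cc`).
#' @export
build_derived_structures <- function(rules, masks, dictionary = empty_dictionary()) {
  stopifnot(is.list(rules), is.list(masks))
  if (length(masks) > 0) {
    g <- masks[[1]]$grid
    for (m in masks[-1]) {
      if (!grid_equal(g, m$grid)) stop("input masks lie on different grids", call. = FALSE)
    }
  }
  outputs <- vapply(rules, function(r) r$output_id, character(1))
  report <- tibble::tibble(output_id = character(), outcome = character(),
                           missing = character(), volume_cc = numeric())
  work <- masks
  for (rule in rules) {
    refs <- unlist(lapply(rule$steps, function(s) s$operands))
    if (rule$output_id %in% refs) {
      stop(sprintf("rule '%s' references its own output", rule$output_id), call. = FALSE)
    }
    res <- execute_rule(rule, work, dictionary)
    if (is.null(res$mask)) {
      report <- dplyr::bind_rows(report, tibble::tibble(
        output_id = rule$output_id, outcome = "flagged",
        missing = paste(unique(res$missing), collapse = ", "),
        volume_cc = NA_real_
      ))
    } else {
      work[[rule$output_id]] <- res$mask
      report <- dplyr::bind_rows(report, tibble::tibble(
        output_id = rule$output_id, outcome = "built", missing = "",
        volume_cc = volume_cc(res$mask)
      ))
    }
  }
  list(masks = work, report = structure(report, class = c("build_report", class(report))))
}

#' Packaged HA-WBRT derivation rules
#'
#' The four derived structures of the packaged hippocampal-avoidance
#' whole-brain template:
#' \describe{
#'   \item{Hippocampi_05}{5 mm PRV margin on the hippocampi.}
#'   \item{NS_Ring_05}{5 mm ring immediately outside the brain PTV, for dose
#'     falloff control.}
#'   \item{PTV_WBopt}{optimization target: PTV minus the hippocampal PRV.}
#'   \item{NS_FaceAvoid}{anterior-inferior avoidance shell: the
#'     anterior-inferior part of Body (face/orbit region) at least 10 mm from
#'     the PTV. The clinical definition is not published; this parametric
#'     construction (anterior_frac 0.5, inferior_frac 0.4 of the PTV bounding
#'     box) is the package's stand-in and is configurable.}
#' }
#'
#' @param target_id Id of the brain PTV (default `"PTV_3000"`).
#' @param body_id Id of the external body contour (default `"Body"`).
#' @param hippocampi_id Id of the combined hippocampi (default `"Hippocampi"`).
#' @return List of four [derivation_rule()] objects.
#' @export
default_hawbrt_rules <- function(target_id = "PTV_3000", body_id = "Body",
                                 hippocampi_id = "Hippocampi") {
  list(
    derivation_rule("Hippocampi_05", list(
      list(verb = "margin", operands = hippocampi_id, mm = 5)
    )),
    derivation_rule("NS_Ring_05", list(
      list(verb = "ring", operands = target_id, inner_mm = 0, outer_mm = 5)
    )),
    derivation_rule("PTV_WBopt", list(
      list(verb = "subtraction", operands = c(target_id, "Hippocampi_05"))
    )),
    derivation_rule("NS_FaceAvoid", list(
      list(verb = "crop_to", operands = c(body_id, target_id),
           anterior_frac = 0.5, inferior_frac = 0.4),
      list(verb = "margin", operands = target_id, mm = 10),
      list(verb = "subtraction", operands = c("$1", "$2"))
    ))
  )
}
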