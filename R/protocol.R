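# Clinical-protocol template parsing.
#
# The XML schema is the package's own, mirroring the content a TPS planning
# template exposes: prescription, target, isocenter rule, default machine,
# field templates and clinical goals. See
# inst/extdata/protocols/ha_wbrt_30gy10fx.xml for the packaged HA-WBRT
# protocol and inst/extdata/protocols/schema.md for the grammar.

xml_attr_num <- function(node, name, where) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) stop(sprintf("missing attribute '%s' on <%s>", name, where), call. = FALSE)
  as.numeric(v)
}

xml_attr_chr <- function(node, name, where) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v) || !nzchar(v)) {
    stop(sprintf("missing attribute '%s' on <%s>", name, where), call. = FALSE)
  }
  v
}

#' Parse a clinical-protocol template
#'
#' Reads the XML planning template into a `clinical_protocol`: prescription
#' (total dose, fractions, dose per fraction, target), default machine, field
#' templates, clinical goals, and the list of structures the protocol expects.
#' Prescription arithmetic (total = fractions x dose/fraction) is validated to
#' 1e-6 Gy.
#'
#' @param document XML text, or a file path to an XML document.
#' @return A `clinical_protocol`: list with `protocol_id`, `prescription`
#'   (list `total_gy`, `fractions`, `per_fraction_gy`, `target_id`),
#'   `machine_id`, `fields` (tibble: `field_id`, `technique`, `gantry_start`,
#'   `gantry_stop`, `rotation`, `collimator`, `couch`, `energy`),
#'   `goals` (tibble: `structure_id`, `metric`, `comparator`, `threshold`,
#'   `units`), `expected_structures` (character).
#' @export
parse_clinical_protocol <- function(document) {
  doc <- if (is.character(document) && length(document) == 1 &&
             !grepl("<", document, fixed = TRUE) && file.exists(document)) {
    xml2::read_xml(document)
  } else {
    xml2::read_xml(paste(document, collapse = "\n"))
  }
  root <- xml2::xml_find_first(doc, "/ClinicalProtocol")
  if (inherits(root, "xml_missing")) {
    stop("document has no <ClinicalProtocol> root element", call. = FALSE)
  }
  protocol_id <- xml_attr_chr(root, "id", "ClinicalProtocol")

  rx_node <- xml2::xml_find_first(doc, "//Prescription")
  if (inherits(rx_node, "xml_missing")) {
    stop("protocol is missing the <Prescription> element", call. = FALSE)
  }
  prescription <- list(
    total_gy = xml_attr_num(rx_node, "totalDoseGy", "Prescription"),
    fractions = as.integer(xml_attr_num(rx_node, "fractions", "Prescription")),
    per_fraction_gy = xml_attr_num(rx_node, "dosePerFractionGy", "Prescription"),
    target_id = xml_attr_chr(rx_node, "target", "Prescription")
  )
  if (abs(prescription$total_gy -
          prescription$fractions * prescription$per_fraction_gy) > 1e-6) {
    stop(sprintf(
      "inconsistent prescription arithmetic: %.6g Gy != %d x %.6g Gy",
      prescription$total_gy, prescription$fractions, prescription$per_fraction_gy
    ), call. = FALSE)
  }

  machine_node <- xml2::xml_find_first(doc, "//Machine")
  if (inherits(machine_node, "xml_missing")) {
    stop("protocol is missing the <Machine> element", call. = FALSE)
  }
  machine_id <- xml_attr_chr(machine_node, "id", "Machine")

  field_nodes <- xml2::xml_find_all(doc, "//Fields/Field")
  if (length(field_nodes) == 0) {
    stop("protocol defines no <Field> elements (at least one is required)", call. = FALSE)
  }
  fields <- purrr::map_dfr(field_nodes, function(fn) {
    technique <- xml_attr_chr(fn, "technique", "Field")
    if (!technique %in% c("arc", "static")) {
      stop(sprintf("unknown field technique '%s' (arc|static)", technique), call. = FALSE)
    }
    gs <- xml_attr_num(fn, "gantryStart", "Field")
    gt <- if (technique == "arc") xml_attr_num(fn, "gantryStop", "Field") else gs
    if (technique == "arc" && isTRUE(all.equal(gs, gt))) {
      stop("arc field must have gantryStart != gantryStop", call. = FALSE)
    }
    if (gs < 0 || gs >= 360) stop("gantryStart must lie in [0, 360)", call. = FALSE)
    tibble::tibble(
      field_id = xml_attr_chr(fn, "id", "Field"),
      technique = technique,
      gantry_start = gs,
      gantry_stop = gt,
      rotation = if (technique == "arc") xml_attr_chr(fn, "rotation", "Field") else "NONE",
      collimator = xml_attr_num(fn, "collimator", "Field"),
      couch = xml_attr_num(fn, "couch", "Field"),
      energy = xml_attr_chr(fn, "energy", "Field")
    )
  })
  bad_rot <- setdiff(unique(fields$rotation), c("CW", "CC", "NONE"))
  if (length(bad_rot) > 0) {
    stop(sprintf("unknown rotation direction '%s' (CW|CC)", bad_rot[1]), call. = FALSE)
  }

  goal_nodes <- xml2::xml_find_all(doc, "//Goals/Goal")
  goals <- if (length(goal_nodes) == 0) {
    tibble::tibble(structure_id = character(), metric = character(),
                   comparator = character(), threshold = numeric(),
                   units = character())
  } else {
    purrr::map_dfr(goal_nodes, function(gn) {
      comp <- xml_attr_chr(gn, "comparator", "Goal")
      if (!comp %in% c("le", "ge")) {
        stop(sprintf("goal comparator must be 'le' or 'ge', got '%s'", comp), call. = FALSE)
      }
      tibble::tibble(
        structure_id = xml_attr_chr(gn, "structure", "Goal"),
        metric = xml_attr_chr(gn, "metric", "Goal"),
        comparator = comp,
        threshold = xml_attr_num(gn, "threshold", "Goal"),
        units = xml_attr_chr(gn, "units", "Goal")
      )
    })
  }

  expected <- xml2::xml_attr(xml2::xml_find_all(doc, "//ExpectedStructures/Structure"), "id")

  structure(
    list(
      protocol_id = protocol_id,
      prescription = prescription,
      machine_id = machine_id,
      fields = fields,
      goals = goals,
      expected_structures = expected
    ),
    class = "clinical_protocol"
  )
}

#' Serialize a clinical protocol back to XML text
#'
#' Inverse of [parse_clinical_protocol()]; `parse(serialize(p))` reproduces
#' `p` for every protocol expressible in the schema.
#'
#' @param protocol A `clinical_protocol`.
#' @return A single XML string.
#' @export
serialize_clinical_protocol <- function(protocol) {
  stopifnot(inherits(protocol, "clinical_protocol"))
  p <- protocol
  num <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  lines <- c(
    sprintf('<ClinicalProtocol id="%s">', p$protocol_id),
    sprintf('  <Prescription totalDoseGy="%s" fractions="%d" dosePerFractionGy="%s" target="%s"/>',
            num(p$prescription$total_gy), p$prescription$fractions,
            num(p$prescription$per_fraction_gy), p$prescription$target_id),
    sprintf('  <Machine id="%s"/>', p$machine_id),
    "  <Fields>"
  )
  for (i in seq_len(nrow(p$fields))) {
    f <- p$fields[i, ]
    lines <- c(lines, sprintf(
      '    <Field id="%s" technique="%s" gantryStart="%s" gantryStop="%s" rotation="%s" collimator="%s" couch="%s" energy="%s"/>',
      f$field_id, f$technique, num(f$gantry_start), num(f$gantry_stop),
      f$rotation, num(f$collimator), num(f$couch), f$energy
    ))
  }
  lines <- c(lines, "  </Fields>", "  <Goals>")
  for (i in seq_len(nrow(p$goals))) {
    g <- p$goals[i, ]
    lines <- c(lines, sprintf(
      '    <Goal structure="%s" metric="%s" comparator="%s" threshold="%s" units="%s"/>',
      g$structure_id, g$metric, g$comparator, num(g$threshold), g$units
    ))
  }
  lines <- c(lines, "  </Goals>", "  <ExpectedStructures>")
  for (s in p$expected_structures) {
    lines <- c(lines, sprintf('    <Structure id="%s"/>', s))
  }
  lines <- c(lines, "  </ExpectedStructures>", "</ClinicalProtocol>")
  paste(lines, collapse = "\n")
}

#' @export
print.clinical_protocol <- function(x, ...) {
  cat(sprintf("<clinical_protocol> '%s': %.4g Gy in %d fx to %s, machine %s, %d fields, %d goals\n",
              x$protocol_id, x$prescription$total_gy, x$prescription$fractions,
              x$prescription$target_id, x$machine_id, nrow(x$fields), nrow(x$goals)))
  invisible(x)
}

#' Path to a packaged example file
#'
#' @param ... Path components under `inst/extdata`.
#' @return Absolute file path.
#' @export
rtplankit_example <- function(...) {
  system.file("extdata", ..., package = "rtplankit", mustWork = TRUE)
}
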