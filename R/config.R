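# Automation configuration: derived-structure rules, KBP-style model
# structure matching map, target dose levels, and algorithm overrides.
# Serialized as YAML; see inst/extdata/configs/ha_wbrt.yaml.

DERIVATION_VERBS <- c("union", "intersection", "subtraction", "xor",
                      "margin", "ring", "crop_to")

#' Declarative rule deriving one structure
#'
#' A rule is an ordered list of steps; each step applies one verb to named
#' structures and/or results of earlier steps (referenced as `"$1"`, `"$2"`,
#' ...). The last step's result becomes the rule output.
#'
#' Verbs: `union`, `intersection`, `subtraction`, `xor` (set algebra);
#' `margin` (`mm` parameter, signed, |mm| <= 50); `ring` (`inner_mm`,
#' `outer_mm`); `crop_to` (keep the part of the first operand inside an
#' axis-aligned half-space region of the second operand's bounding box;
#' parameters `anterior_frac` and/or `inferior_frac` in (0, 1]).
#'
#' @param output_id Name of the derived structure.
#' @param steps List of steps: `list(verb =, operands = character(), ...)`
#'   with verb-specific parameters.
#' @return A `derivation_rule`.
#' @export
derivation_rule <- function(output_id, steps) {
  stopifnot(is.character(output_id), nzchar(output_id), is.list(steps), length(steps) >= 1)
  for (s in steps) {
    if (is.null(s$verb) || !s$verb %in% DERIVATION_VERBS) {
      stop(sprintf("unknown derivation verb '%s'; allowed: %s",
                   s$verb %||% "<missing>", paste(DERIVATION_VERBS, collapse = ", ")),
           call. = FALSE)
    }
    if (is.null(s$operands) || length(s$operands) == 0) {
      stop(sprintf("derivation step with verb '%s' has no operands", s$verb), call. = FALSE)
    }
    if (s$verb == "margin" && abs(s$mm %||% 0) > 50) {
      stop("margin magnitude exceeds the 50 mm sanity bound", call. = FALSE)
    }
  }
  structure(list(output_id = output_id, steps = steps), class = "derivation_rule")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse an automation configuration
#'
#' Reads the YAML automation template: ordered derivation rules, the
#' planning-structure to model-structure map, target dose levels (absolute
#' Gy), optional bilateral evaluation groups, and free-form algorithm
#' overrides. Duplicate rule outputs are rejected.
#'
#' @param document YAML text or a file path.
#' @return An `automation_config`: list with `derivation_rules` (list of
#'   [derivation_rule()]), `model_structure_map` (tibble `planning_id`,
#'   `model_id`), `target_dose_map` (tibble `target_id`, `dose_gy`),
#'   `bilateral_map` (named list of component id vectors),
#'   `algorithm_overrides` (named character).
#' @export
parse_automation_config <- function(document) {
  raw <- if (length(document) == 1 && !grepl("\n", document) && file.exists(document)) {
    yaml::read_yaml(document)
  } else {
    yaml::yaml.load(paste(document, collapse = "\n"))
  }
  rules <- lapply(raw$derivation_rules %||% list(), function(r) {
    steps <- lapply(r$steps, function(s) {
      s$operands <- as.character(unlist(s$operands))
      s
    })
    derivation_rule(r$output, steps)
  })
  outputs <- vapply(rules, function(r) r$output_id, character(1))
  if (anyDuplicated(outputs)) {
    stop(sprintf("duplicate derivation rule output '%s'",
                 outputs[duplicated(outputs)][1]), call. = FALSE)
  }

  msm <- raw$model_structure_map %||% list()
  model_structure_map <- if (length(msm) == 0) {
    tibble::tibble(planning_id = character(), model_id = character())
  } else {
    tibble::tibble(
      planning_id = vapply(msm, function(e) as.character(e$planning), character(1)),
      model_id = vapply(msm, function(e) as.character(e$model), character(1))
    )
  }
  if (any(!nzchar(model_structure_map$planning_id)) ||
      any(!nzchar(model_structure_map$model_id))) {
    stop("model_structure_map entries must be non-empty", call. = FALSE)
  }

  tdm <- raw$target_dose_map %||% list()
  target_dose_map <- if (length(tdm) == 0) {
    tibble::tibble(target_id = character(), dose_gy = numeric())
  } else {
    tibble::tibble(
      target_id = vapply(tdm, function(e) as.character(e$target), character(1)),
      dose_gy = vapply(tdm, function(e) as.numeric(e$dose_gy), numeric(1))
    )
  }

  bilateral <- raw$bilateral_map %||% list()
  bilateral_map <- lapply(bilateral, function(v) as.character(unlist(v)))

  overrides <- raw$algorithm_overrides %||% list()
  algorithm_overrides <- vapply(overrides, as.character, character(1))

  structure(
    list(
      derivation_rules = rules,
      model_structure_map = model_structure_map,
      target_dose_map = target_dose_map,
      bilateral_map = bilateral_map,
      algorithm_overrides = algorithm_overrides
    ),
    class = "automation_config"
  )
}

#' @export
print.automation_config <- function(x, ...) {
  cat(sprintf("<automation_config> %d derivation rules, %d model map entries, %d target dose levels\n",
              length(x$derivation_rules), nrow(x$model_structure_map),
              nrow(x$target_dose_map)))
  invisible(x)
}

#' Load an XML structure dictionary of name synonyms
#'
#' Each `<Structure id="...">` element lists `<Synonym id="..."/>` children.
#' A synonym appearing under two canonical ids is rejected at load.
#'
#' @param document XML text or a file path.
#' @return A `structure_dictionary`: named list mapping canonical id to its
#'   character vector of synonyms.
#' @export
read_structure_dictionary <- function(document) {
  doc <- if (length(document) == 1 && !grepl("<", document, fixed = TRUE) &&
             file.exists(document)) {
    xml2::read_xml(document)
  } else {
    xml2::read_xml(paste(document, collapse = "\n"))
  }
  nodes <- xml2::xml_find_all(doc, "//Structure")
  entries <- stats::setNames(
    lapply(nodes, function(n) xml2::xml_attr(xml2::xml_find_all(n, "Synonym"), "id")),
    xml2::xml_attr(nodes, "id")
  )
  all_syn <- tolower(unlist(entries, use.names = FALSE))
  if (anyDuplicated(all_syn)) {
    stop(sprintf("synonym '%s' maps to more than one canonical id",
                 unlist(entries)[duplicated(all_syn)][1]), call. = FALSE)
  }
  structure(entries, class = "structure_dictionary")
}

#' An empty structure dictionary
#' @return A `structure_dictionary` with no entries.
#' @export
empty_dictionary <- function() structure(list(), class = "structure_dictionary")

normalize_id <- function(x) tolower(gsub("[ _-]", "", x))

#' Resolve a requested structure name against the available structures
#'
#' Deterministic tiered matching: (1) case-insensitive exact; (2) dictionary
#' synonym — the requested id is mapped to its canonical entry (it may itself
#' be a synonym) and all names of that entry are tried case-insensitively;
#' (3) normalized comparison (spaces, underscores and hyphens stripped,
#' case-folded). The first tier with exactly one hit wins; two or more hits
#' within a tier is an ambiguity error. No hit in any tier returns a flagged
#' result.
#'
#' @param requested Structure id requested by a template.
#' @param available Character vector of structure ids present in the case.
#' @param dictionary A `structure_dictionary` (default empty).
#' @return One-row tibble: `requested`, `matched` (NA when none), `tier`
#'   (`"exact"`, `"synonym"`, `"normalized"`, `"none"`), `flagged`.
#' @export
match_structure <- function(requested, available, dictionary = empty_dictionary()) {
  stopifnot(is.character(requested), length(requested) == 1)
  available <- as.character(available)
  result <- function(matched, tier) {
    tibble::tibble(requested = requested, matched = matched, tier = tier,
                   flagged = is.na(matched))
  }
  pick <- function(hits, tier) {
    if (length(hits) >= 2) {
      stop(sprintf("ambiguous %s match for '%s': candidates %s", tier, requested,
                   paste(hits, collapse = ", ")), call. = FALSE)
    }
    result(hits, tier)
  }

  hits <- available[tolower(available) == tolower(requested)]
  if (length(hits) > 0) return(pick(unique(hits), "exact"))

  # tier 2: all names of the canonical entry the requested id belongs to
  names_of <- function(canon) unique(c(canon, dictionary[[canon]]))
  canon_hit <- NULL
  for (canon in names(dictionary)) {
    if (tolower(requested) %in% tolower(names_of(canon))) { canon_hit <- canon; break }
  }
  if (!is.null(canon_hit)) {
    cands <- tolower(names_of(canon_hit))
    hits <- unique(available[tolower(available) %in% cands])
    if (length(hits) > 0) return(pick(hits, "synonym"))
  }

  hits <- unique(available[normalize_id(available) == normalize_id(requested)])
  if (length(hits) > 0) return(pick(hits, "normalized"))

  result(NA_character_, "none")
}

#' Resolve every model-map entry of a configuration
#'
#' One row per `model_structure_map` entry, matched with [match_structure()];
#' unresolved entries are flagged, never dropped. Rows whose planning id is a
#' target carry the dose level from `target_dose_map`.
#'
#' @param config An `automation_config`.
#' @param available Character vector of structure ids present in the case.
#' @param dictionary A `structure_dictionary`.
#' @return Tibble: `planning_id`, `model_id`, `matched`, `tier`, `flagged`,
#'   `dose_gy` (NA for non-target rows).
#' @export
resolve_model_matches <- function(config, available, dictionary = empty_dictionary()) {
  stopifnot(inherits(config, "automation_config"))
  rows <- purrr::map_dfr(seq_len(nrow(config$model_structure_map)), function(i) {
    e <- config$model_structure_map[i, ]
    m <- match_structure(e$planning_id, available, dictionary)
    tibble::tibble(
      planning_id = e$planning_id, model_id = e$model_id,
      matched = m$matched, tier = m$tier, flagged = m$flagged
    )
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(planning_id = character(), model_id = character(),
                          matched = character(), tier = character(),
                          flagged = logical(), dose_gy = numeric()))
  }
  dplyr::left_join(rows, config$target_dose_map,
                   by = c("planning_id" = "target_id"))
}
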