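# Protocol/config/dictionary parsing and structure-name matching.

test_that("the packaged HA-WBRT protocol parses with its template constants", {
  p <- packaged_protocol()
  expect_s3_class(p, "clinical_protocol")
  expect_equal(nrow(p$fields), 3)
  expect_equal(p$fields$collimator, c(345, 15, 90))
  expect_equal(p$prescription$total_gy, 30)
  expect_equal(p$prescription$fractions, 10L)
  expect_equal(p$prescription$target_id, "PTV_3000")
  expect_equal(nrow(p$goals), 7)
})

test_that("protocol parsing enforces presence and prescription arithmetic", {
  base <- readLines(rtplankit_example("protocols", "ha_wbrt_30gy10fx.xml"))
  no_fields <- gsub('<Field .*/>', "", base)
  expect_error(parse_clinical_protocol(no_fields), "no <Field>")

  bad_rx <- gsub('dosePerFractionGy="3"', 'dosePerFractionGy="2"', base)
  expect_error(parse_clinical_protocol(bad_rx), "arithmetic")

  no_rx <- base[!grepl("Prescription", base)]
  expect_error(parse_clinical_protocol(no_rx), "Prescription")
})

test_that("protocols round-trip through serialization", {
  set.seed(5)
  for (trial in 1:5) {
    nf <- sample(1:4, 1)
    fx <- sample(1:20, 1); dpf <- round(stats::runif(1, 1, 4), 2)
    p <- structure(list(
      protocol_id = sprintf("proto_%d", trial),
      prescription = list(total_gy = fx * dpf, fractions = fx,
                          per_fraction_gy = dpf, target_id = "PTV_X"),
      machine_id = sample(c("TB1", "TB2"), 1),
      fields = tibble::tibble(
        field_id = sprintf("F%d", seq_len(nf)),
        technique = sample(c("arc", "static"), nf, replace = TRUE),
        gantry_start = round(stats::runif(nf, 0, 359), 1),
        gantry_stop = round(stats::runif(nf, 0, 359.9), 1),
        rotation = sample(c("CW", "CC"), nf, replace = TRUE),
        collimator = round(stats::runif(nf, 0, 359), 1),
        couch = 0,
        energy = "6X"
      ),
      goals = tibble::tibble(structure_id = "PTV_X", metric = "D2%",
                             comparator = "le", threshold = 37.5, units = "Gy"),
      expected_structures = c("PTV_X", "Body")
    ), class = "clinical_protocol")
    p$fields$gantry_stop[p$fields$technique == "static"] <-
      p$fields$gantry_start[p$fields$technique == "static"]
    p$fields$rotation[p$fields$technique == "static"] <- "NONE"
    # avoid degenerate arcs
    same <- p$fields$technique == "arc" & p$fields$gantry_stop == p$fields$gantry_start
    p$fields$gantry_stop[same] <- (p$fields$gantry_start[same] + 10) %% 360
    rt <- parse_clinical_protocol(serialize_clinical_protocol(p))
    expect_equal(rt$prescription, p$prescription)
    expect_equal(as.data.frame(rt$fields), as.data.frame(p$fields))
    expect_equal(as.data.frame(rt$goals), as.data.frame(p$goals))
    expect_equal(rt$expected_structures, p$expected_structures)
  }
})

test_that("the packaged automation config defines the four HA-WBRT rules", {
  cfg <- packaged_config()
  outputs <- vapply(cfg$derivation_rules, function(r) r$output_id, character(1))
  expect_setequal(outputs,
                  c("Hippocampi_05", "NS_Ring_05", "PTV_WBopt", "NS_FaceAvoid"))
  expect_equal(cfg$target_dose_map$dose_gy, 30)
  expect_true("OpticNerves" %in% names(cfg$bilateral_map))
})

test_that("config parsing rejects duplicates and unknown verbs, allows empty", {
  empty <- parse_automation_config("derivation_rules: []")
  expect_length(empty$derivation_rules, 0)

  dup <- "
derivation_rules:
  - output: A
    steps: [{verb: margin, operands: [X], mm: 3}]
  - output: A
    steps: [{verb: margin, operands: [X], mm: 5}]
"
  expect_error(parse_automation_config(dup), "duplicate")

  bad <- "
derivation_rules:
  - output: A
    steps: [{verb: sculpt, operands: [X]}]
"
  expect_error(parse_automation_config(bad), "allowed")
})

test_that("dictionary loading rejects a synonym under two canonical ids", {
  expect_error(read_structure_dictionary('
<StructureDictionary>
  <Structure id="A"><Synonym id="dup"/></Structure>
  <Structure id="B"><Synonym id="DUP"/></Structure>
</StructureDictionary>'), "more than one")
  d <- packaged_dictionary()
  expect_true("Hippocampi" %in% names(d))
})

test_that("match_structure resolves by tier with ambiguity as error", {
  d <- packaged_dictionary()
  m <- match_structure("Hippocampi", c("Hippocampi", "Brain"), d)
  expect_equal(m$tier, "exact"); expect_false(m$flagged)

  m2 <- match_structure("OpticChiasm", c("Optic Chiasm", "Brain"), d)
  expect_equal(m2$tier, "synonym"); expect_equal(m2$matched, "Optic Chiasm")

  # requested id may itself be a synonym
  m3 <- match_structure("Chiasm", c("OpticChiasm"), d)
  expect_equal(m3$tier, "synonym"); expect_equal(m3$matched, "OpticChiasm")

  m4 <- match_structure("PTV WBopt", c("PTV_WBopt"), empty_dictionary())
  expect_equal(m4$tier, "normalized")

  m5 <- match_structure("Cochlea", c("Brain"), d)
  expect_equal(m5$tier, "none"); expect_true(m5$flagged); expect_true(is.na(m5$matched))

  expect_error(match_structure("ptv", c("PTV", "Ptv"), empty_dictionary()),
               "ambiguous")

  # order-independence of the available list
  m6 <- match_structure("OpticChiasm", c("Brain", "Optic Chiasm"), d)
  expect_equal(m6$matched, m2$matched)
})

test_that("resolve_model_matches yields one flagged-or-matched row per entry", {
  cfg <- packaged_config()
  d <- packaged_dictionary()
  all_present <- c("PTV_WBopt", "Hippocampi_05", "NS_Ring_05", "NS_FaceAvoid",
                   "OpticChiasm")
  rows <- resolve_model_matches(cfg, all_present, d)
  expect_equal(nrow(rows), nrow(cfg$model_structure_map))
  expect_false(any(rows$flagged))
  expect_equal(rows$dose_gy[rows$planning_id == "PTV_WBopt"], 30)
  expect_true(all(is.na(rows$dose_gy[rows$planning_id != "PTV_WBopt"])))

  some <- resolve_model_matches(cfg, setdiff(all_present, "NS_FaceAvoid"), d)
  expect_equal(sum(some$flagged), 1)
  expect_equal(some$planning_id[some$flagged], "NS_FaceAvoid")

  syn <- resolve_model_matches(cfg, c(setdiff(all_present, "OpticChiasm"), "Optic Chiasm"), d)
  expect_equal(syn$tier[syn$planning_id == "OpticChiasm"], "synonym")
})
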