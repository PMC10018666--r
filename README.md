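# rtplankit

Vendor-independent scaffolding for template-guided automated radiotherapy
treatment planning, with hippocampal-avoidance whole-brain radiotherapy
(HA-WBRT) as the packaged use case.

Automated planning tools built on treatment-planning-system APIs interpret a
clinical-protocol template (prescription, target, fields, goals), derive the
optimization structures the template needs, validate the case, lay out the
beams, and evaluate the resulting dose against clinical goals. Everything in
that chain *except* the commercial optimizer is reimplementable in the open,
and that is what this package provides, for physicists and developers who
want to prototype or regression-test planning automation without a TPS:

* **Voxel geometry** — contour ⇄ mask conversion (even-odd rule on voxel
  centers), Boolean combination, exact anisotropic Euclidean margin
  expansion and rings via a distance transform, volumes and centroids.
* **Templates** — XML clinical protocols, YAML automation configs
  (declarative derivation rules, model-structure matching, target dose
  levels), XML structure-synonym dictionaries, tiered deterministic name
  matching with ambiguity-as-error.
* **Structure builder** — rule execution with flag-and-continue semantics;
  the packaged HA-WBRT set derives `Hippocampi_05` (5 mm PRV), `NS_Ring_05`
  (5 mm ring), `PTV_WBopt` (PTV minus PRV) and `NS_FaceAvoid`.
* **Plan skeleton** — isocenter at the target bounding-box center, three
  alternating VMAT arcs (gantry 180.1 → 179.9, collimators 345/15/90 for the
  packaged template), beam's-eye-view jaw fitting over the arc.
* **Validation** — integrity checks with pass/tracked/warning/flag states
  (stale image > 14 days, non-CT series, reused structure set, protocol
  interpretation, goal evaluation) and a parameter-change audit log.
* **Dose evaluation** — sample-based DVHs; D*x*%, D*v*cc, V*x*Gy, Dmin/Dmax;
  homogeneity index `100·(D5% − D95%)/rx`; prescription normalization to
  D95% = rx; exact Wilcoxon signed-rank paired plan comparison.
* **Synthetic phantom** — a seeded HA-WBRT head phantom (brain PTV,
  bilateral hippocampi, optic structures) plus a dose-shape emulator, so the
  whole pipeline runs end to end with no patient data.

The core dose metrics, on the empirical per-voxel distribution of a
structure `S` with `n` voxels:

* `Dx% = max{ d : |{v ∈ S : dose(v) ≥ d}| ≥ n·x/100 }` — the
  `⌈n·x/100⌉`-th largest sample (so `D100%` is the minimum dose),
* `VxGy = 100 · |{v ∈ S : dose(v) ≥ x}| / n`,
* `HI = 100 · (D5% − D95%) / rx`,

and prescription normalization rescales the grid by `rx / D95%(target)`, after
which `V_rx(target) ≥ 95%` holds exactly.

## Worked example

```r
library(rtplankit)

# a seeded synthetic HA-WBRT case and its emulated dose
phantom <- generate_phantom(phantom_spec())
dose    <- generate_dose(phantom, dose_model_spec(seed = 1))

# interpret the packaged clinical protocol and automation template
protocol   <- parse_clinical_protocol(rtplankit_example("protocols", "ha_wbrt_30gy10fx.xml"))
config     <- parse_automation_config(rtplankit_example("configs", "ha_wbrt.yaml"))
dictionary <- read_structure_dictionary(rtplankit_example("dictionaries", "structures.xml"))

# derive the optimization structures
built <- build_derived_structures(config$derivation_rules, phantom$masks, dictionary)
built$report
#> # A tibble: 4 × 4
#>   output_id     outcome missing volume_cc
#>   <chr>         <chr>   <chr>       <dbl>
#> 1 Hippocampi_05 built   ""           29.1
#> 2 NS_Ring_05    built   ""          308.
#> 3 PTV_WBopt     built   ""         1605.
#> 4 NS_FaceAvoid  built   ""          284.

# plan skeleton: isocenter at the PTV center, 3 alternating arcs
layout <- build_fields(protocol, place_isocenter(built$masks$PTV_3000))
layout <- fit_all_jaws(layout, built$masks$PTV_3000)
layout$fields[, c("field_id", "gantry_start", "gantry_stop", "rotation", "collimator")]
#>   field_id gantry_start gantry_stop rotation collimator
#> 1 ARC1            180.1       179.9 CW              345
#> 2 ARC2            179.9       180.1 CC               15
#> 3 ARC3            180.1       179.9 CW               90

# normalize to the 30 Gy prescription and evaluate the packaged goals
norm    <- normalize_prescription(dose, built$masks$PTV_3000, rx = 30)
metrics <- evaluate_metrics(norm$dose, built$masks, protocol$goals, rx = 30,
                            target_id = "PTV_3000",
                            bilateral_map = config$bilateral_map)
metrics[, c("structure_id", "metric", "value", "units")]
#>   structure_id  metric  value units
#> 1 PTV_3000      D2%     30.9  Gy
#> 2 PTV_3000      D98%    28.6  Gy
#> 3 PTV_3000      V30Gy   95.0  %
#> 4 Hippocampi    D100%    7.3  Gy
#> 5 Hippocampi    D0.03cc  8.6  Gy
#> 6 OpticNerves   D0.03cc 16.6  Gy
#> 7 OpticChiasm   D0.03cc 20.6  Gy
#> 8 PTV_3000      HI       2.7  %
check_clinical_goals(protocol$goals, metrics)$state
#> [1] "pass" "pass" "pass" "pass" "pass" "pass" "pass"
```

The target is covered (V30Gy = 95% after normalization, D98% above 25 Gy)
while the hippocampi sit in the carved cold well (minimum dose goal ≤ 9 Gy
met) and the optic structures stay under their 30 Gy maxima — the HA-WBRT
trade-off the template encodes. `run_pipeline()` performs the same chain as
one call (plus validations, audit log, timing and artifact writing), and
`inst/cli/rtplankit.R` exposes it as a command line with
`run | phantom | derive | plan | evaluate | compare` subcommands.

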