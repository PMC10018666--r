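# Automation configuration for the packaged HA-WBRT template.
# Derivation rules execute in order; "$k" references the result of step k
# within the same rule. Margins in mm. The NS_FaceAvoid construction is the
# package's parametric stand-in for the unpublished clinical definition.
derivation_rules:
  - output: Hippocampi_05
    steps:
      - {verb: margin, operands: [Hippocampi], mm: 5}
  - output: NS_Ring_05
    steps:
      - {verb: ring, operands: [PTV_3000], inner_mm: 0, outer_mm: 5}
  - output: PTV_WBopt
    steps:
      - {verb: subtraction, operands: [PTV_3000, Hippocampi_05]}
  - output: NS_FaceAvoid
    steps:
      - {verb: crop_to, operands: [Body, PTV_3000], anterior_frac: 0.5, inferior_frac: 0.4}
      - {verb: margin, operands: [PTV_3000], mm: 10}
      - {verb: subtraction, operands: ["$1", "$2"]}
model_structure_map:
  - {planning: PTV_WBopt, model: PTV_WB_OPT}
  - {planning: Hippocampi_05, model: Hippocampi_PRV05}
  - {planning: NS_Ring_05, model: NS_Ring}
  - {planning: NS_FaceAvoid, model: NS_Face}
  - {planning: OpticChiasm, model: OpticChiasm}
target_dose_map:
  - {target: PTV_WBopt, dose_gy: 30}
bilateral_map:
  OpticNerves: [OpticNerve_L, OpticNerve_R]
algorithm_overrides:
  dose_grid_resolution_mm: "2.5"
  mr_level_smoothing: "default"
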