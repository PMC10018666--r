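# Frozen default dose-emulator parameters for the synthetic HA-WBRT phantom.
# Calibrated once against the packaged clinical-goal set (see the methods
# vignette): prescription plateau with 1.5% ripple, hippocampal cold wells
# deep enough to spare the hippocampi without dragging PTV D98% below goal.
rx_gy: 30
ripple_frac: 0.015         # relative ripple amplitude inside the PTV
ripple_period_mm: 70
cold_well_depth: 0.74      # fraction of rx removed at the hippocampus
cold_well_sigma_mm: 2.5    # Gaussian shoulder width of the well
falloff_length_mm: 25      # exponential dose falloff outside the PTV
falloff_max_mm: 80         # distance cap for the falloff computation
noise_sd_gy: 0.15          # additive Gaussian noise
seed: 20260101
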