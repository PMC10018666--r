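# Frozen default geometry for the synthetic HA-WBRT head phantom.
# All lengths in mm, patient LPS coordinates, axial axis-aligned grid.
grid:
  origin: [-118.75, -118.75, -118.75]   # center of voxel (0,0,0)
  spacing: [2.5, 2.5, 2.5]
  dims: [96, 96, 96]
body:                      # head ellipsoid (external contour)
  center: [0, 0, 0]
  semiaxes: [80, 95, 105]
brain:                     # whole-brain PTV (PTV_3000)
  center: [0, -5, 10]
  semiaxes: [65, 80, 75]
hippocampi:                # bilateral arc tubes, deep-central
  x_offset: 26             # +/- lateral offset of each tube plane
  arc_center_y: 5
  arc_center_z: 5
  arc_radius: 25
  phi_deg: [-125, -55]     # arc angular span in the y-z plane
  tube_radius: 6
  nominal_volume_cc_per_side: 4.0    # design target, clinical-scale hippocampus
optic_nerve:               # straight cylinders along y, below the brain
  x_offset: 12
  z: -75
  y_range: [-60, -35]
  radius: 3
optic_chiasm:
  center: [0, -30, -75]
  semiaxes: [10, 5, 4]
ct:                        # cosmetic two-tissue HU model
  air_hu: -1000
  tissue_hu: 40
  brain_hu: 30
seed: 20260101
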