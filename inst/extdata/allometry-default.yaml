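# Default allometric calibration for treelim. These are the package's
# calibration values for an average, species-independent tree; recalibrate
# any law with fit_scaling_law() and your own data.
height_vs_diameter:
  prefactor: 2.0
  exponent: 0.6666666666666666
  input_units: cm
  output_units: m
basal_flow_small:
  prefactor: 0.00266
  exponent: 2.5
  input_units: cm
  output_units: liters/day
basal_flow_large:
  prefactor: 0.006
  exponent: 2.2
  input_units: cm
  output_units: liters/day
canopy_radius:
  prefactor: 0.1
  exponent: 1.1
  input_units: m
  output_units: m
canopy_depth:
  prefactor: 0.5
  exponent: 1.0
  input_units: m
  output_units: m
root_radius:
  prefactor: 0.2
  exponent: 1.1
  input_units: m
  output_units: m
leaf_count:
  prefactor: 50.0
  exponent: 2.0
  input_units: cm
  output_units: count
crossover_diameter: 15.0
leaf_area_single: 0.0015
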