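# Example kinetox analysis configuration.  Every key is optional; omitted
# keys fall back to the built-in defaults (shown here).
seed: 1
grid_resolution: 0.1          # simulation grid, h
setup:
  medium_volume_mL: 2
  cells_per_well: 2.0e+06
  reporting_unit_cells: 1.0e+05
paths:
  output_dir: kinetox-output
  # kinetics_with_cells: my_kinetics.csv   # omit to use synthetic data
  # kinetics_cell_free:  my_cellfree.csv
  # viability:           my_viability.csv
synthetic:
  noise_cv_kinetics: 0.15     # lognormal CV of kinetic measurements
  noise_sd_viability: 8       # Gaussian SD of viability, % points
  replicates: 3               # kinetic replicates (destructive wells)
  viability_replicates: 6     # samples per viability point
fit:
  n_starts: 8                 # multi-start BFGS
  pin: [kdeg]                 # cell-free estimates held fixed with cells
  floor: 1.0e-03              # quantification floor, nmol
  inclusion:                  # restrict the with-cells training data
    max_time_h: null
    nominal_uM: null
    scenario_labels: null
dose_response:
  metrics: [nominal, cmax_medium, cmax_cells, auc_medium, auc_cells]
  viability_nominal: [0, 0.625, 1.25, 1.9, 2.5, 3.75, 5, 10, 15]
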