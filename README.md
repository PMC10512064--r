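# kinetox

In vitro distribution kinetics and kinetics-derived dose metrics for
repeat-dose toxicity assays.

## The problem

Plate-based toxicity assays usually report potency against the *nominal*
concentration — what was pipetted into the medium.  For lipophilic test
chemicals this misrepresents the dose at the cells: the chemical binds to
the well-plate plastic, accumulates in cells across repeated medium
changes, and degrades abiotically in the medium.  The apparent potency
then drifts with the exposure scenario (24 h vs 48 h vs 7-day repeated
dosing vs washout), which confounds assay comparisons, potency ranking,
and quantitative in vitro–in vivo extrapolation (QIVIVE).

`kinetox` is for in vitro toxicologists and modellers who want to correct
for this.  It models the well as a linear three-compartment system —
medium, cells, plastic — with first-order transfer and abiotic degradation
of the medium:

    dA_med/dt  = -(ka_cell + ka_plastic + kdeg) A_med + kd_cell A_cell + kd_plastic A_pl
    dA_cell/dt =   ka_cell A_med - kd_cell A_cell
    dA_pl/dt   =   ka_plastic A_med - kd_plastic A_pl

with complete medium exchanges as dosing/washout events.  Rate constants
are calibrated to compartment measurements by BFGS on log-parameters,
minimizing relative errors balanced per time point, in two stages
(cell-free system first).  Calibrated trajectories yield four dose metrics
— Cmax and AUC, in medium and in cells — and viability dose–response
curves are re-fit (four-parameter logistic, variable slope) against each
metric.  If the cell-associated Cmax drives cytotoxicity, the IC50s on
that scale cluster across exposure scenarios while nominal-scale IC50s
fall with repeated dosing.

A synthetic-data generator emulates the underlying destructive-sampling
study (kinetics and viability, with known ground truth), so the whole
pipeline is testable without any external data.

## Worked example

```r
library(kinetox)
res <- run_full_analysis(output_dir = "kinetox-output")
print(res)
```

```
kinetox analysis (seed 1, config 580b75d9)
calibrated rates (1/h):
   ka_cell    kd_cell ka_plastic kd_plastic       kdeg
  0.158100   0.126600   0.264000   0.888100   0.007701
IC50 by dose metric and scenario:
      metric scenario_label     ic50 ambiguous
     nominal           24 h   2.9680     FALSE
     nominal           48 h   2.8680     FALSE
     nominal            7 d   1.5870     FALSE
     nominal           7 dW   1.5410     FALSE
 cmax_medium           24 h   2.9680     FALSE
 ...
  cmax_cells           24 h   0.1362     FALSE
  cmax_cells           48 h   0.1316     FALSE
  cmax_cells            7 d   0.1304     FALSE
  cmax_cells           7 dW   0.1266     FALSE
  auc_medium           24 h  62.0900     FALSE
  auc_medium           48 h 107.4000     FALSE
  auc_medium            7 d 282.3000     FALSE
  auc_medium           7 dW 370.5000     FALSE
   auc_cells           24 h  56.2300     FALSE
   auc_cells           48 h 115.0000     FALSE
   auc_cells            7 d 333.9000     FALSE
   auc_cells           7 dW 460.3000     FALSE
```

Reading the table: on the **nominal** scale the IC50 falls almost 2-fold
from acute (2.97 µM at 24 h) to repeated exposure (1.59 µM at 7 d) — the
chemical *appears* to get more toxic with time.  On the **cmax_cells**
scale (nmol per 100,000 cells) the four scenarios cluster at 0.127–0.136:
the cells respond to the same internal peak dose everywhere, and the
apparent time-dependence was accumulation, not sensitization.  The
**AUC**-scale IC50s increase monotonically with exposure duration, which
is why a cumulative metric does not transfer across scenarios.  (This run
calibrates on synthetic data generated under seed 1; the generator's true
rates are `ka_cell = 0.155`, `kd_cell = 0.134`, `ka_plastic = 0.282`,
`kd_plastic = 1.0`, `kdeg = 0.0058`, and the true cmax-cells IC50 is
0.13.)

The pieces are available individually — `simulate_scenario()` /
`solve_piecewise_exact()` for trajectories, `fit_cell_free()` /
`fit_with_cells()` / `fit_two_stage()` for calibration, `dose_metrics()`
and `dose_metric_table()` for dosimetry, `fit_4pl()`, `compute_icx()` and
`reexpress_dose_response()` for dose–response, and
`generate_kinetics_dataset()` / `generate_viability_dataset()` /
`write_mock_study()` for synthetic studies.  A thin command-line wrapper
lives at `inst/scripts/kinetox-cli.R` (subcommands `run`, `simulate`,
`calibrate`, `metrics`, `doseresponse`, `synth`).  See the methods
vignette (`vignettes/kinetox-methods.Rmd`) for the model, assumptions, and
numerical choices.

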