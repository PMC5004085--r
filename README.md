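# hcofam

Family-structure robustness analysis for half-center oscillator (HCO)
model databases.

A half-center oscillator is a pair of reciprocally inhibitory neurons
producing alternating bursting — the core circuit of many central pattern
generators, such as the leech heartbeat timing network. Brute-force
parameter-space studies simulate such a model at every point of a large
grid of maximal-conductance scale factors, label each instance by its
activity (silent, tonically spiking, plateau, asymmetric, endogenously
bursting, functional or realistic HCO), and then ask how *robust* the
bursting rhythm is to parameter variation.

`hcofam` implements the full desk-scale analysis pipeline around that
question:

- **Grid bookkeeping** — parameter grids of conductance scale fractions
  plus the leak reversal potential, analytic point counts, enumeration,
  and a versioned TSV instance-table format
  (`grid_spec()`, `grid_size()`, `enumerate_grid()`, `write_instance_db()`).
- **Burst metrics** — spike detection at −20 mV, burst segmentation
  (≥3 spikes, ≥1 s interburst gap), burst period between middle spikes,
  duty cycle, intraburst spike frequency, amplitude/period regularity,
  and the phase between the two cells
  (`detect_spikes()`, `segment_bursts()`, `burst_characteristics()`).
- **Activity classification** — the full label set with the physiological
  realism criteria: period 5–15 s, mean spike frequency 8–25 Hz, duty
  cycle 50–70 %, phase within [0.45, 0.55]
  (`classify_trace_pair()`, `realistic_flags()`).
- **One-parameter families** — instances identical in every varied
  parameter except one *defining* parameter form a family; families are
  interrupted when grid levels are missing inside their permissible range
  (`build_families()`, `tabulate_sizes()`, `attribute_missing()`,
  `select_ensembles()`).
- **Robustness measures** — for a size threshold *n*:
  *X*, the number of families with more than *n* members; *Y*, the number
  of those that are noninterrupted; *Z*, the number of missing members
  that keep functional HCO bursting; and the weighted score
  *R* = *w*<sub>X</sub>·*X* + *w*<sub>Y</sub>·*Y* + *w*<sub>Z</sub>·*Z*
  (`robustness_measures()`, `robustness_score()`, `robustness_report()`).
- **Period sensitivity** — polynomial fits (degree ≤ 5) of period versus
  conductance fraction along each family, classified high / medium / low
  by the steepest descending tangent against thresholds −2.5 and −0.4
  (`classify_curve()`, `classify_family_curves()`).
- **Simulation contract** — a config-driven two-cell conductance-based
  ODE engine (stiff solver via `deSolve::lsoda`) with a packaged
  surrogate model, shared deterministic initial state, and per-point
  conductance scaling (`read_model_config()`, `simulate_pair()`).
- **Synthetic data** — a deterministic alternating-burst trace generator
  with exact ground truth for validating the metrics, and a
  phenomenological grid→activity response for building labeled databases
  with known family structure (`synthesize_trace_pair()`,
  `make_synthetic_db()`).

Everything is tidyverse-native: data-frame-first functions returning
tibbles, `autoplot()`/`plot_*()` views per result type, and
`tidy()`/`glance()` methods for the robustness report.

## Worked example

The package ships the census tables of a published-scale study of a
10,485,760-instance HCO database (99,066 realistic HCOs) as fixture
data, so the headline numbers can be reproduced directly:

```r
library(hcofam)

fx <- load_fixture_tables()
h_row <- dplyr::filter(fx$table1, param == "h")

# group size: sum of size x family-count over the h row
sum(h_row$size * h_row$total)
#> [1] 99066

# measures at threshold n = 4 (families with more than four members)
robustness_measures(h_row, n = 4)
#> # A tibble: 1 x 4
#>       n     X     Y     Z
#>   <dbl> <dbl> <dbl> <int>
#> 1     4  4669  1729    NA

# Eq.-1 score with weights (0.5, 0.5, 0) and the census Z value
robustness_score(4669, 1729, Z = 8945, weights = c(0.5, 0.5, 0))
#> [1] 3199
normalize_score(3199, 4669)
#> [1] 0.685
```

A complete scaled-down run on a toy grid:

```r
spec <- grid_spec(fractions = c(0.75, 1.25, 1.75),
                  e_leak_levels = c(-60, -55))   # 4,374 points
db   <- make_synthetic_db(spec, seed = 1)
fams <- build_families(dplyr::filter(db, label == "rHCO"), "h", spec)
tabulate_sizes(fams)
classify_family_curves(fams, db)                  # period sensitivity
```

## Documentation

The methods vignette (`vignettes/hcofam-methods.Rmd`) describes the burst
definitions, classification criteria, family construction, the robustness
and sensitivity measures, the simulation contract and the synthetic-data
generator, including all numerical conventions and known limitations.
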