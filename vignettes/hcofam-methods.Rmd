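---
title: "Methods: burst analysis, families and robustness in hcofam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst analysis, families and robustness in hcofam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hcofam)
```

This vignette states, in one place, every definition, convention and
numerical choice the package uses. The running example is a half-center
oscillator (HCO): two reciprocally inhibitory model neurons whose
alternating bursting is analyzed over a large grid of maximal-conductance
scale factors.

## The parameter grid

Seven maximal conductances are varied as scale fractions of a canonical
set, together with the leak reversal potential:

| parameter  | canonical value | default grid levels |
|------------|-----------------|---------------------|
| `x_P`      | g_P = 7 nS      | 0–1.75, step 0.25 (8 levels) |
| `x_K2`     | g_K2 = 80 nS    | same |
| `x_Leak`   | g_Leak = 8 nS   | same |
| `x_CaS`    | g_CaS = 3.2 nS  | same |
| `x_h`      | g_h = 4 nS      | same |
| `x_SynS`   | g_SynS = 60 nS  | same |
| `x_SynG`   | g_SynG = 30 nS  | same |
| `e_leak`   | −60 mV          | −70, −65, −60, −55, −50 mV |

Four further conductances stay fixed (g_Na = 200, g_CaF = 5,
g_K1 = 100, g_KA = 80 nS). The full default grid has
8^7 × 5 = 10,485,760 points; fixing both synapses at zero leaves the
8^5 × 5 = 163,840-point synapse-free subset. `grid_size()` computes these
analytically; `enumerate_grid()` instantiates a grid in mixed-radix order
with `x_P` varying slowest and `e_leak` fastest. Desk-scale examples in
this package use 2–3 levels per parameter (e.g. 3^7 × 2 = 4,374 points);
those sizes are this package's own choice of tractable test scale, not a
property of the method.

## Burst definitions

All analysis runs on uniformly sampled voltage traces of the two cells.

* **Spike** — one contiguous excursion above the −20 mV threshold; its
  time is the local maximum, its amplitude the peak voltage
  (`detect_spikes()`).
* **Burst** — a maximal run of at least 3 spikes whose inter-spike gaps
  are strictly below the 1 s minimum interburst interval. A gap of
  exactly 1 s terminates the burst. Bursts whose first or last spike lies
  within 1 s of the recording boundary are discarded as possibly
  truncated (`segment_bursts()`).
* **Middle spike** — the spike at 0-based index ⌊(n−1)/2⌋ of an n-spike
  burst, i.e. the lower median for even n.
* **Burst period** — mean interval between middle spikes of consecutive
  bursts; `cv_period` is the sd/mean of those intervals (0 when only one
  interval exists; undefined below two bursts, reported as `NA` with
  `period_defined = FALSE`, never an error).
* **Duty cycle** — 100 × mean burst duration / mean period (%).
* **Spike frequency** — mean spikes-per-burst divided by mean burst
  duration (Hz).
* **Amplitude CV** — within each burst, sd/mean of spike amplitudes
  measured as height above the −20 mV detection threshold; the cell's
  value is the maximum over bursts. Measuring above threshold keeps the
  ratio well conditioned when spike peaks ride near 0 mV (sd/|mean peak
  voltage| would divide by ≈ 0).
* **Phase** — for each burst of cell B, the delay of its middle spike
  after the preceding middle spike of cell A, normalized by that A cycle,
  averaged over B bursts.

Instance-level characteristics average period, frequency and duty cycle
over the two cells and take the larger (worse) of the two CVs.

## Activity classification

`classify_trace_pair()` assigns one of nine labels. An HCO requires, for
both cells: at least two complete bursts within the final 40 s of the
recording, amplitude CV < 0.07 in every burst, period CV < 0.05; jointly
a phase in [0.45, 0.55]; and at least one synapse present. It is
*realistic* (`rHCO`) when period ∈ [5, 15] s, spike frequency ∈ [8, 25]
Hz and duty cycle ∈ [50, 70] % (all closed intervals), otherwise
*functional* (`fHCO`), with the failed criteria recorded as a
three-character mask (`"P-D"` style; `realistic_flags()`). With both
synapses absent the same regularity criteria define `burster` /
`realistic_burster` (duty cycle not required). `silent` means no spikes,
`plateau` a ≥1 s supra-threshold depolarization without three spikes,
`spiking` spikes without qualifying bursts, `asymmetric` cells that
differ or alternate outside the phase/CV criteria, and `other` is the
fallback.

## One-parameter families

Fix a *defining* parameter. Instances of one activity group (say, all
rHCOs) that agree on every other varied parameter form a **family**
(`build_families()`; the grouping key is `context_key()`). The family's
**permissible range** runs from its smallest to largest defining-parameter
value; grid levels absent *inside* that range make the family
**interrupted**; levels outside it are missing-outside members.
One-member families count as noninterrupted by convention. Every group
member belongs to exactly one family, giving the partition identity
Σ size × count(size) = group size, which the test suite checks on every
synthetic database.

`attribute_missing()` looks up each missing member's instance in the full
database and records its label, and — for members that remain functional
HCOs — which physiological criteria they fail. `select_ensembles()` keeps
noninterrupted families above a size threshold whose context conductances
are all nonzero, optionally requiring a given synapse-free counterpart
label for every member.

## Robustness measures

For a size threshold *n* (default interest: *n* = 4):

* **X** — families with more than *n* members,
* **Y** — noninterrupted families with more than *n* members,
* **Z** — missing members of those families whose instances keep
  functional HCO bursting,

combined as the weighted score **R = w_X·X + w_Y·Y + w_Z·Z** with
non-negative weights summing to 1 (default (0.5, 0.5, 0));
`normalize_score()` reports R relative to a chosen denominator to three
decimals. By default `Z` counts only interruptions (missing members
inside the permissible range, `z_scope = "inside"`); the
`"all_missing"` switch includes out-of-range missing members. The
distinction matters because a published Z can mix both readings; the
package makes the choice explicit rather than silent.

With the packaged census tables (`load_fixture_tables()`; md5-verified
TSVs): the h row gives X = 4,669 and Y = 1,729 at n = 4, the score
R = 0.5·4,669 + 0.5·1,729 = 3,199, normalized 3,199/4,669 = 0.685; the
enforced-correlation census (X = 53, Y = 51, Z = 2) gives R = 52.

## Period sensitivity of family curves

For every family with ≥3 members, the period-versus-fraction curve is
fitted with a polynomial of degree min(5, members − 1)
(`pracma::polyfit`). The *steepest descending tangent* over the family
span is the minimum of the fitted derivative, evaluated on a 1,000-point
grid plus the derivative's analytic critical points (so the minimum
cannot slip between grid points). Classes: **high** at slope ≤ −2.5 s per
fraction unit, **low** at ≥ −0.4, **medium** between. On exactly linear
curves the fitted slope equals the analytic slope to ~1e−12, which the
tests verify at 1e−9.

## Simulation contract

`read_model_config()` parses a YAML description of a two-cell
conductance-based model: capacitance (nF), currents with maximal
conductance (nS), reversal potential (mV) and sigmoid gates
inf(V) = 1/(1 + exp(−(V − vhalf)/k)) with constant, sigmoid or Gaussian
time constants (s); graded synapses s′ = (act(V_pre) − s)/τ and
spike-mediated synapses s′ = act(V_pre)(1 − s)/τ_rise − s/τ_decay; and a
map from grid parameters to current names. Units combine as
nS·mV/nF = mV/s.

`simulate_pair()` scales the mapped conductances by a grid point's
fractions (both cells always identical), integrates with
`deSolve::lsoda` (default rtol 1e−6, atol 100×rtol) from a shared
initial state, and returns the final recording window re-zeroed in time.
The shared state (`make_initial_state()`) integrates the canonical model
for `t_init` seconds from documented defaults — cell A at −40 mV, cell B
at −60 mV, gates at steady state, synaptic drives 0 — so one cell starts
active and the other inhibited; it is deterministic and cached.

The packaged surrogate model (`surrogate_config()`) is an original
parameterization assembled for exercising this contract: a fast Na/K1
spike generator, persistent Na, a slowly inactivating Ca current, a slow
K2 current whose voltage-dependent time constant (slow buildup when
depolarized, fast unloading when inhibited) terminates bursts, an
h-current escape from inhibition, leak, and both synapse kinds. At the
canonical point it produces alternating bursting with period ≈ 8.0 s,
spike frequency ≈ 24 Hz, phase 0.50 and period CV ≈ 0.

**Limitations.** The surrogate's duty cycle (≈ 40 %) sits below the
realistic 50–70 % band and its within-burst spike amplitudes decline as
the adaptation current builds (amplitude CV ≈ 0.5), so the strict
classifier files the canonical surrogate pair under `spiking`, not
`rHCO`. This is deliberate: the surrogate demonstrates the simulation and
analysis contract, and the classifier is required to be strict about
imperfect bursting. Database-scale analyses in this package therefore use
the phenomenological response below, not ODE sweeps.

## Synthetic data

Two generators with exact ground truth support testing:

* `synthesize_trace_pair()` builds a stereotyped alternating-bursting
  pair from `burst_spec()` (defaults: period 10 s, duty 60 %, spike
  frequency 15 Hz, phase 0.5, spike peak 0 mV, burst plateau −45 mV,
  baseline −60 mV, dt 1 ms, 60 s). Spikes are narrow Gaussian bumps
  (width 4 ms), evenly spaced so the spike span equals the nominal burst
  duration and the middle spike sits at the burst center — the burst
  metrics recover the specification parameters to sampling precision.
  Noise requires an explicit seed and never touches the global RNG.
* `grid_response()` / `make_synthetic_db()` label grid points by an
  ordered phenomenological rule set (silence at very low `x_P`,
  plateau at `x_K2` = 0, spiking at weak synapses, asymmetry at low
  `x_CaS`, otherwise bursting) with period/frequency from a linear
  response around the canonical point (period 10 s, frequency 15 Hz,
  duty 60 %). The period coefficients make period fall with `x_h`,
  `x_K2`, `x_Leak` and rise with `x_CaS`, `x_P`, `x_SynS`. These
  defaults are fixed study conditions: they guarantee monotone
  period-versus-`x_h` family curves and a known family structure, which
  the oracle-based tests exploit. The generator emulates the *structure*
  of a brute-force database (labels, characteristics, families,
  interruptions), not the dynamics of any particular neuron model.

## Reproducibility conventions

All stochastic entry points (`burst_spec()`, `make_synthetic_db()`) take
a mandatory integer seed and restore the RNG state afterwards
(`withr::with_seed`). Fixture tables are md5-verified at load. The
instance-table TSV format is versioned by a header line and validated on
read, with malformed rows reported by number.
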