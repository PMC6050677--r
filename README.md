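# mvlogic

Multi-valued logical (generalized discrete / Thomas-style) modeling of
regulatory networks, for systems biologists who know a circuit's wiring but
not its kinetic parameters. Networks are signed, thresholded digraphs whose
nodes take integer levels `0..rho`; dynamics are driven by logical `K`
parameters — one target level per (node, active-regulator-subset) — that
stand in for synthesis/decay ratios. The package provides:

* the **image function** `y_i = K[i, I(x)]` and single-step **tendency**
  `f(x_i) = x_i + sign(y_i - x_i)`;
* three update schemes: synchronous, fully asynchronous, and an
  asynchronous **priority-class scheme with residual update memory** —
  per-node delay counters `d_i` that make slow nodes wait out idle
  iterations before responding to a persistent command;
* exhaustive state-transition-graph construction with **attractor**
  detection (terminal strongly connected components, Tarjan) and basins;
* **feedback-circuit** enumeration with realizable-parity functionality
  testing, and exhaustive `K`-space **tuning** against qualitative
  behavior constraints (e.g. "exactly two cyclic attractors"), including
  calibration of an environmental input;
* a **single-fault stochastic model** (per-iteration probability `eps` that
  one active node disobeys its tendency) with Monte Carlo estimation of the
  attractor-to-attractor transition matrix `pi[i,j] = P(settle in i | start
  in basin j)` and **Markov-chain** escape analysis;
* executable models of the **HPA axis** (CRH, ACTH, cortisol, glucocorticoid
  receptor) at rest, under persistent stress, and under receptor blockade,
  plus a random-network generator for property tests.

## Worked example

```r
library(mvlogic)

m <- hpa_resting_model()
stg <- build_stg(m, "priority")         # memory-extended transition graph
att <- find_attractors(stg)
print(att)
#> 2 attractor(s) under priority update:
#>   #1 cyclic (6 states): [0002] [0012] [0112] [1002] [1102] [1112]
#>   #2 cyclic (6 states): [0010] [0011] [0021] [0110] [0120] [0121]
```

States are `[CRH ACTH CORT R]`. The two cycles are the model's two
regulatory programs: a *pathological* regime (#1) where cortisol oscillates
low (0–1) with the receptor saturated at 2, and a *healthy* regime (#2)
where cortisol oscillates mid-to-high (1–2) with the receptor low. No
fault-free transition connects the two regimes.

How entrenched is each regime under 5% decisional noise?

```r
tm <- attractor_transition_matrix(m, eps = 0.05, reps = 1000, seed = 42)
print(tm)
#> Attractor transition matrix (eps = 0.05, 1000 reps/state, horizon 1):
#>        basin
#> settled     A1     A2
#>      A1 0.9915 0.0005
#>      A2 0.0085 0.9995
```

Starting anywhere in the healthy basin, a single fault event carries a
0.0005 chance of capture by the pathological regime; escape in the other
direction is ~17x more likely (0.0085) but still rare. Evolving the matrix
as a Markov chain quantifies long-run occupancy:

```r
mk <- markov_evolve(tm, p0 = 1, n_steps = 200)   # start pathological
print(mk)
#> Markov chain over 2 attractors, 200 steps
#>   escape half-time (from attractor 1 ): 84
#>   limiting distribution: 0.0599 0.9401
```

The environmental-input workflow reproduces the model's context dependence:
`calibrate_input(m, "Stress", target = "CRH")` enumerates the 16 stress-CRH
context assignments (census: 4 with two cyclic attractors, 4 with one cycle
plus a stationary point, 8 stationary-only) and retains the two
rest-compatible sets whose stress-locked stationary states overlap the
resting regimes; `hpa_stress_model()` and `hpa_drug_model()` package the
calibrated conditions. Under `Drug = 1` the pathological cycle ceases to be
an attractor and the healthy cycle is the single remaining regime.

Models round-trip through a YAML/JSON schema (`read_model()` /
`write_model()`; see `inst/extdata/hpa_rest.yaml`), graphs export to DOT and
GraphML (`export_stg()`), and a thin CLI (`exec/mvlogic`, or `cli_main()`)
exposes `attractors`, `simulate`, `tune`, `calibrate-input`,
`mc-transition`, `markov` and `fixtures` subcommands.

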