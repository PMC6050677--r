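---
title: "Multi-valued logical modeling of regulatory networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-valued logical modeling of regulatory networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mvlogic)
```

## The formalism

`mvlogic` implements the generalized (multi-valued) logical formalism for
regulatory networks. A network is a signed, thresholded, directed graph: node
$v$ takes integer levels $0..\rho_v$, and an interaction $j \to i$ carries a
sign $\alpha_{ij} \in \{+,-\}$ and a threshold $\theta_{ij}$. The interaction
*context* is active when $S^{\alpha_{ij}}(x_j, \theta_{ij}) = 1$, i.e. when
$x_j \ge \theta_{ij}$ for activators and $x_j < \theta_{ij}$ for inhibitors
(an absent inhibitor is an active inhibitory context).

The dynamics are driven by the **image function**. For every non-input node
$i$ and every subset $I$ of its regulators, a logical parameter
$K_{i,I} \in \{0..\rho_i\}$ gives the level node $i$ tends toward when
exactly the contexts in $I$ are active; $K_{i,\varnothing}$ is the basal
value. These parameters discretize the ratio of synthesis to decay kinetics
of a piecewise-linear rate law, which is why a complete $K$ table — one entry
per regulator subset — is required explicitly rather than defaulted: the
tuning machinery enumerates exactly this space, and silent defaults would
hide its size. Because exactly one subset is active in any state, the image
reduces to a single table lookup; a test asserts on random networks that this
lookup equals the literal sum-over-subsets evaluation.

Level changes are gradual: the **tendency** moves each node one step toward
its image per update, never a jump, so trajectories pass through every
intermediate level. Nodes with no incoming interaction are *inputs*: they
have no image and are frozen at their assigned level, which is why every
analysis is run per input assignment (the state space decomposes).

## Update schemes

Three schemes decide which nodes apply their tendency:

* **synchronous** — all nodes at once; deterministic, every state has
  exactly one successor (so the transition graph has $|E| = |V|$);
* **fully asynchronous** — any single off-image node may move; a state with
  $k$ off-image nodes has $k$ successors;
* **priority with memory** — asynchronous, but gated by per-node *residual
  memory* counters $m_i$ initialized at configured delays $d_i \ge 1$. Only
  nodes whose memory attains the network minimum are eligible to move
  (ties: all eligible). After each transition the counters update per node
  with two flags, F1 = "the image changed since the previous iteration" and
  F2 = "the node's level did not change in this transition":
  just-updated nodes reset to $d_i$; nodes with an unchanged, persistent
  command count down toward 1; nodes whose command changed while they held
  still count back up toward $d_i$. At the start of a run F1 is defined
  false (the previous image is a sentinel) so that memory starts at $d_i$.

Two textual ambiguities in the memory rules were resolved as follows and are
deliberate, documented readings rather than switches:

* F1 compares the *image values* of consecutive iterations by whole-value
  inequality (true when they differ). The alternative gloss — agreement of
  direction — would prevent the countdown under a persistent command that
  produces the delayed-activation behavior the scheme exists for.
* When no *eligible* node can move but some slow node is off its image, the
  scheme takes an **idle** iteration in which only the memory counters
  advance. This is how a slow node's delay is actually consumed; without
  idle steps a state whose only off-image node is slow would deadlock.
  A state whose every non-input node sits on its image is stationary.

Priority dynamics therefore live on *extended states* $(x, m, y^{prev})$.
The state transition graph (STG) is built over the extended space reachable
from every run-start state; attractors are detected there and **projected**
to level space for reporting (projections identical in level space are
merged). The projection convention is a choice — published split-range
reports are drawn in level space — not an inference about how the original
figures were produced.

## Attractors and basins

Attractors are the terminal strongly connected components of the STG: no
edge leaves the component. A singleton with no change-producing successor is
a *stationary* (regular) attractor; anything larger is *cyclic* (singular).
Components are found with an iterative Tarjan algorithm, linear in
$|V| + |E|$; the suite validates it against a brute-force transitive-closure
oracle on over a hundred random digraphs and against igraph's SCC
decomposition. Basins are computed by backward traversal from each attractor;
because the schemes are nondeterministic a state may reach several
attractors, so both the full reachable-set map and the exclusive restriction
are exposed — conditioning a transition-probability estimate needs an
unambiguous basin label, while reporting wants the full map.

Exhaustive STG construction is exponential in network size ($m^n$ states for
$n$ nodes of $m$ levels); `build_stg()` refuses spaces above a configurable
cap rather than degrade silently. The bundled analyses involve 36 level
states (a few hundred extended states), far below the cap.

## Feedback circuits and parameter tuning

Sustained oscillation requires a functional negative feedback circuit and
multistability a functional positive one, so exhaustive $K$-space searches
are prefiltered by circuit functionality. Elementary circuits are enumerated
by a rooted depth-first search (each cycle found once, at its smallest
node); the nominal parity of a circuit is the product of its edge signs.

Functionality is tested operationally. For the circuit edge $j \to i$, let
$\theta_{out}(i)$ be the threshold of the circuit edge leaving $i$, and
compare the image of $i$ in the high-$j$ and low-$j$ contexts, for every
activity assignment of $i$'s other regulators (enumerated exhaustively and
independently per circuit node): the edge acts *positively* when
$K_{high} \ge \theta_{out} > K_{low}$ and *negatively* when
$K_{low} \ge \theta_{out} > K_{high}$. Crucially, the realized direction may
differ from the nominal edge sign: a $K$ table can step *down* across a
nominally activating threshold. During development a full-enumeration
candidate showed exactly this — a nominally positive self-loop realized as a
decreasing step that sustained a two-state limit cycle — so circuits report
their set of *realizable parities* (`circuit_parities()`), and the prefilter
asks for a realizable negative (oscillation) or positive (multistability)
parity. With that refinement the prefilter-necessity property — no sampled
candidate without a realizable negative circuit exhibits a cyclic attractor,
none without a realizable positive one exhibits multiple attractors — holds
across the sampled enumeration, in line with circuit theory on local
interaction graphs. On binary networks with sign-consistent tables the test
reduces to the classical circuit-characteristic conditions.

`tune_parameters()` walks a deterministically ordered Cartesian product of
free $K$ slots (the full resting HPA space has $4 \cdot 16 \cdot 9 \cdot 81
= 46{,}656$ candidates; the count is always reported rather than assumed,
since slot-space definitions vary), applies the prefilter, and evaluates a
behavior constraint on each surviving candidate's attractor report. The
bundled constraint `"bistable_cyclic"` asks for exactly two cyclic
attractors.

### Calibrating an environmental input

`calibrate_input()` adds (or accepts) a binary input acting on one target
node and enumerates all $K$ assignments of the target's context slots — 16
for a two-regulator binary target. Each candidate is classified by its
attractor census with the input held active, and retained when

1. with the input inactive its attractor report equals the base model's
   (rest-compatibility), and
2. with the input active it has at least one stationary state whose
   projection lies **on** a resting attractor cycle (a stress-potentiated
   stable state overlapping a resting regime).

Both clauses are operational interpretations. The second deliberately asks
for *one* on-cycle stationary state rather than coverage of both regimes:
on the bundled model the stricter reading retains nothing (one of the
overlap states sits in the pathological *basin*, not on the cycle), while
the implemented reading retains exactly two sets whose signatures match the
published stress phenotypes — a *normal tone* set that preserves a cyclic
attractor alongside a pathological stationary point, and a *heightened
sensitivity* set whose attractor space collapses to stationary points only.
The stress fixture is generated by running this calibration, not by
hard-coding guessed values.

## The stochastic fault model

Biological decision-making is noisy; the fault model perturbs the dynamics
with a per-iteration probability $\varepsilon$ of one node disobeying its
tendency. Only *active* nodes — those with at least one incoming interaction
whose source is at or above threshold — may fault; the activity test uses
the level comparison $x_w \ge \theta$ for inhibitory edges too (the literal
reading; an "active context" reading would differ only for inhibitors, and
the choice is isolated in one place). Among active nodes one is selected
uniformly; a faulted node holds still when commanded to move, and is
displaced when at equilibrium — up from 0, down from $\rho_v$, to either
neighbor with equal probability from an interior level. The faulted tendency
is substituted before the scheme's transition; if the scheme does not update
the faulted node that iteration, the fault has no effect then (the
composition order is not dictated by the formalism; this is the package's
documented choice).

A **run** applies `horizon` faulted iterations from an initial state, then
relaxes fault-free until an attractor is entered. The default is
`horizon = 1`: each run carries at most one fault event. This is the
single-fault reading — one fault at a time per simulation — and it keeps the
estimated transition probabilities in the small-perturbation regime; with
long faulted horizons the estimates saturate toward the chain's stationary
mixture and stop measuring attractor robustness (at 100 faulted iterations
the escape probability from the saturated-receptor regime rises from ~0.01
to ~0.66). `horizon` remains a parameter, and estimates should always be
read as conditional on the run protocol.

`attractor_transition_matrix()` estimates
$\pi_{ij} = P(\text{settle in } i \mid \text{start in basin } j)$
by Monte Carlo over every exclusively-basined initial state (1000
repetitions per state by default); columns sum to one, replicate counts are
retained, and a fixed seed reproduces the matrix bit for bit. For speed the
simulator first *compiles a fault kernel*: the closure of the extended state
space under both normal and faulted transitions, with exact per-state
successor distributions at rate $\varepsilon$ and at rate 0, and the
fault-free terminal components labeled by attractor. Monte Carlo runs then
reduce to indexed categorical walks, so the full 36-state, 1000-repetition
analysis takes about a second. `settle_distribution()` runs the same
protocol from arbitrary start states — used to start the drug-condition
model from the resting model's attractor states.

`markov_evolve()` iterates an occupancy distribution through a
column-stochastic matrix, reporting the trajectory, the first step at which
the escape probability from the initially occupied attractor reaches one
half, and the limiting distribution (fixed-point iteration, tolerance
$10^{-12}$; validated against the two-state closed form to $10^{-10}$).

## The bundled HPA models

The hypothalamic-pituitary-adrenal axis fixture has four variables — CRH
(0–1), ACTH (0–1), cortisol CORT (0–2) and the glucocorticoid receptor R
(0–2) — wired as the classic cascade with negative feedback: CRH stimulates
ACTH, ACTH stimulates CORT, CORT represses CRH and up-regulates R, R
represses ACTH and sustains itself. Single-output nodes necessarily use
threshold 1; the dual-output nodes split their thresholds (CORT: 1 to CRH,
2 to R; R: 1 to ACTH, 2 to itself) so that each feedback loop can become
active. The $K$ table is the published feasible parameterization; the
priority delays put CRH, ACTH and R in the fast class ($d = 1$) and the
peripherally released CORT in the slow class ($d = 4$).

Under priority-with-memory update the resting model supports exactly two
cyclic attractors with a split CORT range: a *healthy* cycle (CORT 1–2, R
oscillating 0–1) and a *pathological* cycle (CORT 0–1, R saturated at 2).
The two regimes are fully separated — no transition edge connects them or
their basins.

* `hpa_stress_model(tone)` adds a binary `Stress` input activating CRH,
  with CRH contexts fixed by the calibration above.
* `hpa_drug_model()` adds a binary `Drug` input inhibiting R. The published
  account never prints the drug-context $K$ values; the fixture caps R's
  image at 1 in drug-exposed contexts, the minimal encoding that destroys
  the self-sustaining R = 2 context while leaving the healthy cycle (which
  never needs R = 2) untouched. Its validation is behavioral: with the drug
  active the pathological cycle is no longer an attractor and exactly the
  healthy cycle remains; with the drug inactive the model reduces exactly
  to the resting model.
* `random_model()` draws small random networks (random signs, thresholds,
  complete random $K$ tables) for property tests. It emulates the
  *structure* of regulatory models — not data: there is no measurement
  noise, no time series, no parameter uncertainty. Passing property tests
  therefore certifies the algorithms on the formalism's own terms, not
  goodness-of-fit to any biological recording.

## Numerical and scale choices

* All state spaces in the tests are exhaustive and small: 36 level states
  for the HPA models (a few hundred extended states; ~400 in the fault
  kernel closure), $\le 27$ states for random 3-node property models, and
  random digraphs up to 200 vertices for the SCC oracle checks. The
  prefilter-necessity property is checked on random samples of 60–150
  candidates from the 46,656-candidate enumeration; the full sweep is
  exposed through `tune_parameters()` for users who want it.
* Monte Carlo estimates use 1000 repetitions per initial state at
  $\varepsilon = 0.05$, matching the published protocol; with 36 initial
  states this is 36,000 runs, a one-to-two-second computation on the
  compiled kernel.
* Ties among eligible nodes are never broken by a fixed ordering: graph
  construction explores all branches and trajectory simulation chooses
  uniformly at random, to avoid biasing the nondeterminism the formalism
  relies on.
* Probabilities smaller than about $10^{-4}$ are at the resolution limit of
  the replicate counts; treat the smallest matrix entries as order
  estimates.

## Known limitations

* Time is event counting — the number of sequential transitions — not
  physical time; no continuous-time or Gillespie semantics is offered.
* Attractor detection is explicit-state; networks beyond ~20 binary-node
  equivalents need symbolic methods out of scope here.
* The stress calibration's retention rules are qualitative
  interpretations; alternative operationalizations can be evaluated through
  the full classification table the calibration returns.
* The healthy-to-pathological entry probability is structurally limited by
  the single door into the saturated-receptor regime (a direct fault on R
  at an interior equilibrium), so persistent stress does not raise the
  entry rate in this implementation even though it reshapes the attractor
  repertoire; the drug and rest orderings of escape and relapse are
  reproduced.
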