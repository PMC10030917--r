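---
title: "Boolean network dynamics, attractor sampling and phenotype statistics with bnsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Boolean network dynamics, attractor sampling and phenotype statistics with bnsim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bnsim)
```

# The modeling framework

`bnsim` simulates Boolean regulatory networks: each molecular species is a
node that is ON (expressed and active) or OFF (absent or inactive), and a
logic gate over its regulators determines its next state.  The package is
built for the class of models used to study mechanosensitive cell-fate
decisions — epithelial–mesenchymal transition (EMT), contact inhibition,
cell-cycle progression and apoptosis — where a handful of environmental
input nodes (ECM stiffness, growth factors, cell density, external
ligands) select among multistable phenotype repertoires.

A model is a `BooleanModel`: ordered nodes, per-node regulators in
declaration order, the rule expression, and a compiled truth table.
Tables are indexed with the *first* regulator as the most significant
bit.  This convention is arbitrary but fixed and documented, so tables,
serializations and canonical attractor identifiers are reproducible
across machines and runs.  Gates with more than 20 regulators are
refused at compile time (their tables would hold over a million rows);
none of the models this package targets comes near that limit.

## Environmental inputs and state-space partition

An input node is detected automatically: a node whose only regulator is
itself with identity logic (`A *= A`, how BooleanNet-style files encode
held inputs), or a node referenced as a regulator without a rule of its
own.  Both routes are accepted and the loader records which one applied;
an explicit declaration overrides detection.  Inputs are held fixed by
the *environment context* during dynamics; the full state space is
partitioned into one subspace per input combination, and attractors are
reported per context.  Clamping a subset of inputs (e.g. a death ligand
locked OFF) restricts the partition and halves the enumeration per
clamped bit.

# Update schemes

Four engines share one driver:

* **Synchronous** — every non-input node updates simultaneously from the
  previous state; deterministic, used for attractor detection.
* **Noisy synchronous** — after each synchronous step every non-input
  node flips independently with probability `pNoise` (default 0.02, the
  value used throughout sampling).  Noise never touches inputs: flipping
  an input would silently move the trajectory between environment
  subspaces and corrupt per-context sampling.  This is a deliberate
  design choice, stated here because the alternative (noising every
  node) looks superficially more faithful but breaks the partition
  invariant.
* **Random-order asynchronous** — nodes update one at a time in a fresh
  uniformly random order each step, each node seeing all earlier updates
  within the step.
* **Biased asynchronous** — as above, but a small condition-dependent
  list of nodes is forced to the start or end of the order.  Cell-cycle
  logic needs this: fully random orders generate biologically impossible
  event sequences (cytokinesis before anaphase, replication licensing
  mid-mitosis) that inflate error rates.  Start-listed nodes go first in
  listed order; end-listed nodes go last with the first listed updated
  *last*; conditions (`IF_ON`, `IF_OFF`, `ALWAYS`) are evaluated on the
  state at the start of the step, i.e. on the node's "correct" pre-update
  state, not mid-step.  A node selected by both lists is placed by its
  start rule, and the bias constructor warns when the two rules can ever
  fire together.

Fixed points are invariant under all four engines — a property the test
suite checks on every fixture and on random networks across hundreds of
sampled orders.

All randomness (order shuffles, noise flips, stochastic inputs, KD/OE
draws) is drawn from R's global RNG in a fixed documented sequence
(inputs first, then the engine update, then noise, then overrides), so a
single `set.seed()` makes any run bitwise replayable.

# Attractor detection

Attractor detection is synchronous-only; asynchronous engines are for
time-course experiments.  The primitives:

* `descendToAttractor()` iterates the synchronous map with hash-based
  cycle detection until a state repeats (budget $10^6$ steps; exceeding
  it signals a pathological instance rather than looping silently).
* `enumerateAttractors()` descends from *every* state of a context's
  subspace with memoized labelling — the exhaustive oracle, capped at 22
  free nodes (16 MB of labels) by default.
* `sampleAttractors()` is the workhorse for large models: per context it
  runs `nRnd` noisy trajectories of `nSeries` steps from uniform random
  initial states, pauses at every visited state (the initial one
  included — a harmless superset of pausing only at post-step states)
  to descend deterministically into its basin, and optionally also
  descends from every single-node flip of the visited state.  The
  neighborhood scan is what finds small basins the noisy dynamics never
  enters; with it, the sampler finds every attractor whose basin
  contains at least one sampled state or neighbor.  Defaults
  `nRnd = 200`, `nSeries = 5`, `pNoise = 0.02` are the standard sampling
  configuration for these models.  Basin memberships are memoized per
  context, so repeated pauses in the same basin cost one descent.
* `convergenceGrid()` re-runs the sampler over an `nRow x nCol` grid of
  `(nRnd, nSeries)` values (default 15 x 15 in steps of 5, i.e. 5–75)
  and reports the per-run attractor count as a convergence heatmap plus
  the union table.
* `environmentTransitionMap()` flips one environmental input at a time
  from each attractor and descends in the new context — an efficient way
  to discover live-cell attractors in environments dominated by huge
  apoptotic basins, flagging any target the sampler missed.

Attractors are canonicalized: the cycle is rotated so the
lexicographically minimal state (ties broken by minimal concatenation)
comes first, and the identifier is a pure function of the cycle and its
context.  Identifiers are therefore content-addressed and *stable across
independent sampling runs* — unlike run-local integer IDs, which the
experiment-file driver still accepts for convenience (they index the
cached, canonically sorted attractor table, and the cache is invalidated
by the model's content hash when rules change).

# Module isolation and gate surgery

Removing regulators from a gate (module isolation, link-removal mutants)
freezes the removed inputs.  Among the $2^r$ frozen assignments the
package keeps the one that (a) leaves every remaining regulator
functional if any assignment can, and (b) maximizes the entropy of the
reduced gate, $H_G = -p\log p - (1-p)\log(1-p)$ with $p$ the OFF-output
fraction.  Numerical choices, all tested: the functionality requirement
is a hard filter relaxed only when unsatisfiable; the log base is
irrelevant to the argmax and natural log is used with $H(0)=H(1)=0$ by
continuity; entropy ties break to the lexicographically smallest frozen
assignment (removed regulators in declaration order, 0 before 1), making
the reduction deterministic; removing *several* regulators is one joint
optimization over all $2^r$ assignments, which may differ from
removing them one at a time — the joint semantics is the contract.
Removing every regulator freezes the gate to its majority output (tie
toward OFF) with a warning.  `isolateModule()` applies this per module
node; nodes fed exclusively from outside the module become environmental
inputs of the isolated model, so the module's own response to those
signals remains explorable.  Combining link removal with module
isolation in a single call is deliberately not supported — the two
operations do not commute, and forcing them through one call would hide
the order dependence.

Mutant ensembles implement three error kinds — node locks (random bit),
link removals (reduction as above), single truth-table-row flips
(Hamming distance exactly 1 per flip) — never targeting environmental
inputs, so the environment stays controllable across an ensemble.

# Perturbation experiments

*Non-saturating inputs.* A Boolean input is ON or OFF; intermediate
signal strength is modeled by toggling the input ON with a per-step
probability, i.i.d. across steps.  This mimics a signal near the
inflection point of its dose–response curve, where downstream
transmission is intermittent and noisy.  Probabilities 0 and 1
reproduce constant inputs exactly.

*Partial knockdown / overexpression.* A non-input node is forced OFF
(KD) or ON (OE) with a per-step probability, otherwise obeying its rule
— the Boolean analogue of incomplete chemical inhibition or siRNA
silencing, as opposed to a genetic null (probability 1).  Overrides are
applied after the engine update, so an override wins within its step;
this ordering (inputs, engine, noise, overrides) is a package-level
contract since the dominance semantics of "forcing" a node requires the
override to have the last word.

*Pulse experiments.* The standard reversible-environment timeline: 50
baseline steps, one input flipped for a chosen duration (at most 350),
baseline restored out to 400 total steps.

*Scans.* `scanEnvironment()` sweeps one input's ON-probability over a
grid (default 0–100% in 10-point steps), holding the other inputs at
base probabilities, optionally crossed with a KD/OE probability axis,
and reports tidy per-level statistics.

# Phenotype and event statistics

Phenotypes are user-defined signatures — named lists of (node, required
bit) constraints, matched conjunctively; the seven standard signatures
(CIP, noCIP, Migratory, Non-migratory, Epithelial, Mesenchymal,
Hybrid_EM) ship in `inst/extdata` and bind to any model that carries the
referenced marker nodes.  Signatures need not be exclusive and a state
may match none; for the mutually exclusive EMT trio the dwell fractions
therefore sum to at most 1, the deficit being time in transition.

Cell-cycle events are scored by *declarative detectors* (data, not
code): each fires on a rising edge of a trigger node, subject to
state conditions at the trigger step and to pulses required or
forbidden in the window since a reference edge.  The four defaults —
normal cycle completion, G2→G1 reset with re-replication, aberrant
mitosis (anaphase without kinetochore attachment), failed cytokinesis —
target the standard marker-node names of the deposited cell-cycle
models and are validated on scripted marker sequences with known
counts.  The operational definitions are this package's own; the event
*names* and their biological meaning are standard, but any published
description of them leaves the trigger conditions open, so the
detectors are shipped as overridable data rather than hard-coded logic.

`runPhenotypeStatistics()` accumulates live-cell time across
apoptosis-restarted runs until a minimum live-step target is reached
(figure-scale runs use $10^5$ steps; the test suite uses $10^3$–$10^4$
to keep runtimes in seconds).  The apoptotic state itself is not live
time, restarts resume from the experiment's initial condition, and an
environment where every run dies immediately is *flagged* degenerate
with `NA` dwell fractions — never silently reported as zeros.  Event
rates are normalized per minimum cell-cycle length (21 steps, the
period of the proliferative limit cycle in the deposited models), so a
rate of 1.0 means one event per fastest-possible cycle.

# The EMT switch fixture

`buildEmtSwitch()` returns a self-contained tri-stable module over ten
marker nodes.  Two-node staircases encode three-level species: `ZEB1`
(moderate) and `ZEB1_H` (high), `N_bcatenin` and `N_bcatenin_H`, with
the invariant high ⇒ base in every reachable attractor.  The gates
encode the cascading switch: miR-34 ON unless SNAI1 or ZEB1; SNAI1 ON
once miR-34 is lost (its inducers NF-κB/Pak1 and the GSK3β brake are
frozen at permissive values in the isolated module); SNAI1 → Twist1 →
SNAI2 → moderate ZEB1; high ZEB1 requires high nuclear β-catenin;
E-cadherin mRNA is repressed cooperatively by SNAI1 with high ZEB1.

Two encoding decisions deserve a note.  First, the literature leaves
the miR-200 maintenance gate ambiguous (p21 interference versus c-Myb
induction, with high Zeb1 overriding either).  The fixture encodes the
variant in which only high ZEB1 silences *actively transcribed*
miR-200, while moderate ZEB1 with SNAI1 and Twist1 can *maintain*
silencing once established:

```
miR_200 *= not ZEB1_H and (miR_200 or not (SNAI1 and Twist1 and ZEB1))
```

Second, the high-β-catenin gate uses the junction-free branch of the
prose (`N_bcatenin and not miR_200`): adding an explicit
E-cadherin-repression requirement creates a fourth fixed point (a
hybrid-like state with silenced miR-200 but intact E-cadherin) that the
tri-stable switch should not have.  With the encoding shipped, the
module has exactly three synchronous attractors, all fixed points —
epithelial, hybrid E/M, mesenchymal — verified exhaustively over all
$2^{10}$ states in the tests and the acceptance script.  The former
external inputs are substituted into the gates rather than carried as
frozen constant nodes, so the fixture has one environment context and
its state space is exactly the published one.

# The random-network generator

`generateRandomNetwork()` supplies the oracle substrate: seed-
deterministic networks with a chosen number of identity-self-loop
inputs, 1–K regulators per gate sampled uniformly from all nodes, and
truth tables drawn with a chosen ON-bias.  Two canonicalizations keep
serialization exact: constant tables drop their (vacuous) regulators,
and an accidentally drawn identity self-loop is replaced by
self-negation so it does not read back as an environmental input.
These networks emulate the *dynamical* structure of regulatory models —
multistability, small basins, mixed fixed points and cycles — but not
their biological features: no modular organization, no canalizing-gate
enrichment, no two-node staircases, no designed input semantics.
Passing the sampler-vs-oracle and invariance suites on them therefore
demonstrates correctness of the machinery on harder-than-biological
state spaces (random networks are enriched for the small basins the
sampler's neighborhood scan exists for); it does not by itself validate
any biological claim of a specific model.

# Problem sizes and budgets

The shipped tests and the acceptance script size their simulations to
run in seconds to a few minutes on one core: exhaustive oracles use
8–12 free nodes (256–4096 states per context), sampler comparisons use
100 random networks at the default sampling parameters, gate-reduction
oracles use 500 random 4-input gates with all two-regulator removals,
concentration checks use $2\times10^4$–$5\times10^4$ steps with
$3\sigma$ binomial bounds, and statistics runs use up to $5\times10^4$
live steps.  These sizes were chosen as the smallest that make the
binomial bounds sharp and the coverage claims exhaustive; all scale
linearly if larger runs are wanted.

# Known limitations

* Attractor detection is synchronous; asynchronous attractors (loose
  attractors of the asynchronous transition graph) are out of scope, as
  are stable-motif and trap-space methods and exact basin-size
  measurement.
* The deposited 136- and 150-node mechanosensitive EMT models are
  loaded from their rule files when present; the package does not
  re-derive their full rule sets, and checks that need them report the
  files' absence explicitly instead of failing.
* Probabilistic inputs are i.i.d. per step; temporally correlated
  signals are not modeled.
* The experiment-file dialect covers the sampling, module, pulse,
  mutant-ensemble, stochastic-draw and one-input statistics-scan
  directives; model-metadata dialects (layout, citations) and figure
  rendering are out of scope — artifacts are plain CSV with embedded
  model hash and seed.

# A worked example

```{r example}
emt <- buildEmtSwitch()
emt
atts <- enumerateAttractors(emt)
length(atts)
sig <- structure(defaultSignatures()[c("Epithelial", "Mesenchymal",
                                       "Hybrid_EM")],
                 class = "phenotypeSignatures")
vapply(atts, function(a) classifyState(attractorStates(a)[1, ], sig),
       character(1))
```

```{r pulse}
m <- parseBooleanNet("I1 *= I1\nA *= not B or I1\nB *= not A")
px <- pulseExperiment(m, c(I1 = 0L, A = 1L, B = 0L), "I1",
                      duration = 100)
rle(as.integer(px$input[-1]))$lengths  # 50 baseline, 100 flipped, 250 back
```
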