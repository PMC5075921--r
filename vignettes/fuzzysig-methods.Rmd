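---
title: "Knowledge-guided fuzzy logic modeling of signaling networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-guided fuzzy logic modeling of signaling networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzysig)
```

# The problem

Canonical signaling pathways curated from the literature are generic maps:
signed, directed graphs that accumulate evidence across many cell types and
conditions. They rarely predict how a *particular* cell line responds to a
*particular* perturbation. Purely data-driven network inference has the
opposite weakness: phosphoproteomic perturbation datasets are small, so
networks learned from data alone are fragile and hard to interpret.
`fuzzysig` implements a hybrid: a literature-derived **prior knowledge
network (PKN)** with per-edge confidence scores constrains the search, and
an executable **fuzzy logic model** is calibrated against steady-state or
time-series perturbation data. Because the fit can be scored on *aligned*
time series, the method can recover feedback loops, which steady-state
regression cannot.

# Prior confidence scores and network compression

Each reaction in a pathway resource is endorsed by publications. A
publication endorsing many distinct reactions is classified
**high-throughput** (`classify_publication()`, default cutoff 111
reactions, the 90th percentile of reactions-per-publication in a large
pathway-database snapshot; `ht_threshold_from_counts()` recomputes it for
any other snapshot). Reactions endorsed only by low-throughput studies
score 0, 0.8, 0.9, 0.95, 0.95 for 0–4+ endorsements; only high-throughput,
0, 0.25, 0.5, 0.75, 0.85; mixed endorsements take the low-throughput base
plus 0.05 per high-throughput study, capped at 0.95 (`score_reaction()`).
The cap encodes that no literature evidence is taken as certainty.

Proteins that are neither stimulated, inhibited nor measured
("undesignated") are unidentifiable pass-throughs. `compress_network()`
removes them iteratively: linear cascade nodes, converging relays
(several in, one out) and diverging relays (one in, several out). Each
merge of two tandem edges keeps the **minimum** of the two confidences —
the bottleneck of the path — and composes signs multiplicatively.
Nodes with several incoming *and* several outgoing edges are kept: merging
them would manufacture an all-pairs clique the prior never claimed. Where
the source material leaves choices open we fixed them as package policy:
sign composition is multiplicative (standard signed-path semantics), nodes
are visited in sorted order to a fixed point (deterministic, idempotent),
duplicate merged edges keep the larger confidence, and self-loops arising
from merges are dropped as unidentifiable.

# The fuzzy logic model

A model over $m$ nodes is three $m \times m$ matrices: adjacency $B$
($b_{ij}=1$ iff $i$ regulates $j$), signs $R$ ($r_{ij}=1$ activation, $0$
inhibition) and clause membership $C$. Regulators of $j$ with equal
$c_{ij}$ are ANDed; distinct clauses are ORed, i.e. every update rule is a
DNF in which each regulator appears in exactly one AND clause. The
distinct gate structures for indegree $k$ are therefore the set partitions
of $k$ elements — Bell$(k)$ of them (`enumerate_gate_encodings()`).

Continuous signal propagation uses the normalized Hill transfer

$$ f(x) = \frac{x^p}{x^p + h^p}, \qquad f(h) = \tfrac12,\; f(0)=0,\; f(x) \in [0,1), $$

with activation effect $f(x_i)$ and inhibition effect $1-f(x_i)$; AND is
`min`, OR is `max`. The Hill coefficient $p$ (steepness) is fixed at 2 by
default; the sensitivity $h$ (midpoint) is one global model parameter
optimized over the discrete grid $0.2, 0.3, \ldots, 0.8$. We use this
simple Hill form because it satisfies both defining properties (unit
range, midpoint at $h$) on the *entire* grid; the constrained-normalized
variant used in some kinetic-modeling work is undefined once
$h^p \ge 1/2$ (e.g. $p=2$, $h=0.8$) and was therefore rejected. A
per-edge $h$ is deliberately not implemented — it would multiply the
search space without support from the data sizes this method targets.

In **boolean mode** the transfer is the identity, so a fitted model run on
binary states behaves exactly as a Boolean network (with the Hill form
$f(1) < 1$, so bypassing — not thresholding — the transfer is the only
exact reduction).

Simulation is synchronous. For steady-state data every condition clamps
the stimulated receptors at their stimulus values and chemically inhibited
nodes at 0, all other nodes start at 0, and updates run until the maximum
absolute state change falls below $\varepsilon = 10^{-6}$ or $5m$
iterations elapse; non-convergence (oscillation around a feedback loop) is
flagged, never an error, and the last state is used by the fit layer. For
time-series data, measured nodes start at their first experimental value,
everything else at 0, and the simulation produces three times as many
points as the experiment ($3 n_y$) so the alignment has room to warp.
Asynchronous updating is out of scope: it is nondeterministic and
computationally prohibitive at these problem sizes.

# Scoring a candidate network

Steady-state fits use the mean squared error over all
(condition, measured node) cells. Time-series fits use **dynamic time
warping**: the experimental series $y$ and simulated series $z$ are
aligned by the minimum-cost monotone, continuous warp path with pinned
endpoints; the local cost is the squared difference and the reported loss
is the accumulated cost divided by the path length $S$, so losses are
comparable across alignments of different lengths. Ties between
minimal-cost paths go to the shorter path, then to the diagonal step.
Normalization by $S$ and pinned endpoints are package conventions (the
alternatives are not recoverable from first principles); both are fixed
constants, and `timeseries_loss()` exposes an optional true sliding
window (`window`, `stride`) for users who want the minimum loss over
window placements instead of the default full-window alignment — the
default window of $3 n_y$ equals the whole simulated series.

The knowledge-guided objective is

$$ \min_{B, C, R, h} \; \sum_j L(\mathbf y_j, \mathbf z_j)
   \; + \; \gamma \sum_{i,j} |b_{ij} - w_{ij}|
   \; + \; \lambda \sum_j \max(0,\; d_j - d_j^{\max}), $$

where $w_{ij} \in [0,1]$ is the prior confidence (0 for pairs absent from
the prior) and $d_j^{\max}$ is the knowledge-derived indegree cap.
Including a confidence-$w$ prior edge costs $(1-w)$, excluding it costs
$w$, and a non-prior edge costs 1; with binary confidences the penalty
reduces exactly to the qualitative agree/disagree count against the prior
edge set and its complement, so the quantitative prior is a strict
generalization of the classical informative prior on edge sets. The
indegree term penalizes only the *excess* over the cap — a node may
exceed its cap if the data demand it. With equal trust in both kinds of
knowledge $\gamma = \lambda$, the package default (0.5, the value used
throughout the synthetic study).

# Search

All unknowns are integers (edge bits, sign bits, clause labels, the grid
index of $h$), so fitting is a constrained nonlinear integer program. It
is solved by a **multi-restart genetic algorithm**: tournament selection,
uniform crossover, per-gene mutation (default rate one over the
chromosome length), elitism of 2, and independent restarts seeded
`seed`, `seed + 1`, …. The prior-support chromosome joins every initial
population, which accelerates convergence without constraining the
reachable space. Decoding is canonical: clause genes are reduced modulo
the realized indegree and renumbered by first appearance, so label
permutations decode to identical gates; sign genes of prior edges can be
pinned (`fix_prior_signs`), but are free by default since the data may
overrule a curated sign. Results are a pure function of inputs and seed.

`exhaustive_fit()` enumerates the entire space (parent subsets × signs ×
gate partitions × $h$ grid) on small problems and serves as the GA's
optimality oracle in the test suite; the GA itself carries no guarantee,
which is why the package ships the oracle rather than trusting specific
GA settings. The candidate universe defaults to all ordered pairs (the
calibrated model may need edges absent from the prior) and can be
restricted for large problems.

# Synthetic benchmarks

The generators produce every input the method needs. `toy9_network()` is
the bundled 9-node, 10-edge benchmark with two stimulated inputs, a
negative feedback loop `c -> h -> j -| c` and one AND gate
`(c AND d) -> f`; beyond those structural facts its topology is a
synthetic stand-in defined by this package. The benchmark protocol
generates 5 Boolean trajectories of 10 synchronous states from random
initial states, randomly keeps 6 or 7 time points of each (always the
initial state) to mimic sparse experimental sampling, and fits with
$d^{\max} = 2$, $\gamma = \lambda = 0.5$. Priors are sampled by
`perturb_prior()`: a fraction of true edges, plus noise edges drawn from
non-true ordered pairs, all with Uniform(0,1) confidences — so even true
prior edges carry imperfect, randomly scaled evidence. Recovery is scored
by **structural distance** (edge additions plus deletions, ignoring signs
and gates). Steady-state panels (`make_steady_state_panel()`) simulate
conditions to steady state and optionally add Gaussian noise truncated to
$[0,1]$; the truncation is an artifact choice documented here — the
Boolean-trajectory study itself is noise-free.

What these benchmarks do *not* emulate: measurement noise structure of
real phosphoproteomics, dropout, unmeasured confounders, or non-binary
baseline activity. Passing them shows the estimator recovers structure
under its own generative assumptions, not that it is robust to real-data
pathologies.

The test suite runs the recovery experiment at prior ratios 0 and 1 with
noise ratios 0 and 1.5, 20 repeats per cell, 5 GA restarts (population
40, 60 generations) — sizes chosen so the full suite runs on a laptop
core in minutes while the Wilcoxon comparison between ratio-1 and
ratio-0 recovery is still decisive. The GA-vs-oracle battery uses 30
seeded 3–4-node problems with restricted candidate universes so the
exhaustive enumeration stays around $10^3$–$10^5$ models.

# Significance testing and cell-fate prediction

`random_prior_null()` asks whether the learned fit could have come from
prior structure alone: it generates random priors with the same node and
edge counts (every node incident to at least one edge; stimulated nodes
source-only; confidences permuted from the true prior's scores), refits
under each, and reports the z-score of the true data loss against the
null losses plus an empirical p-value.

`predict_cell_fates()` converts a calibrated model to a Boolean network,
wires fate nodes (e.g. apoptosis, proliferation, cell-cycle arrest) from
their upstream signaling proteins with OR gates, initializes measured
proteins from binarized data (threshold 0.5, configurable — the data are
assumed already normalized to (0,1)) and all other proteins from
independent Bernoulli(0.5) draws, and runs each replicate to its
attractor with cycle detection. A fate counts as "on" at a fixed point if
its node is true; on a cyclic attractor the default rule counts it true
when true in at least half the cycle's states (a strict
fixed-point-only mode is available) — cycles are a real outcome of
synchronous Boolean dynamics and silently discarding them would bias the
fractions. Fractions are taken over many replicates (10,000 in the
reference protocol) per experimental time point, and
`fate_correlation()` compares predicted and observed fate trajectories by
Pearson correlation, optionally dropping predicted time points to absorb
the delay between signaling changes and observable phenotype changes.

# Numerical and degenerate-input conventions

* States always lie in $[0,1]$: `min`/`max` of values in $[0,1]$ and the
  Hill transfer cannot leave the interval.
* Nodes without regulators hold their value; stimulated nodes are
  clamped for whole simulations; a chemically inhibited node is clamped
  to 0 in the conditions that inhibit it.
* Ties in the genetic algorithm's best-of-restarts selection break by
  lower prior penalty, then fewer edges, then lexicographic chromosome —
  full determinism.
* An empty prior is legal (pure data-driven fit with a sparsity-like
  penalty of $\gamma$ per edge); an empty candidate universe errors.
* Endorsement counts above 4 saturate the score table; merged parallel
  edges keep the larger confidence; compression of an already-compressed
  network is the identity.

# Problem sizes used by the shipped checks

The acceptance checks in `tests/testthat/test-acceptance.R` and the
reproduction script `scripts/acceptance.R` use: the 9-node benchmark with
5 trajectories subsampled to 6–7 points (80 GA fits for the prior/noise
sweep), 30 GA-vs-oracle problems on 3–4 nodes, 200 random DTW pairs of
length ≤ 5 against an exhaustive path oracle, exhaustive truth-table
checks up to indegree 3, and 10,000 Boolean replicates for the fate
sampler. These sizes are the package's chosen benchmark conditions and
are documented here so results are reproducible exactly.
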