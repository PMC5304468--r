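---
title: "Planning experiments with causal graphs and research maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planning experiments with causal graphs and research maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalplanr)
```

# The problem

A neuroscientist planning the next experiment faces two linked questions:
what do the published findings, taken together, still leave undetermined
about the causal structure of the system, and which feasible experiment
would reduce that indeterminacy (or strengthen the evidence) the most?
`causalplanr` operationalizes both questions for the small, desk-scale
systems (three to five phenomena) at which a scientist actually reasons:
a signalling cascade, a pathway fragment, a behavioural circuit.

Two representations carry the analysis:

* a **causal graph** — a directed graph over named variables in which an
  edge asserts a direct causal effect; the hypothesis object;
* a **research map** — an annotated evidence graph whose edges are typed
  excitatory, inhibitory, or no-connection, carry the experiment records
  that support them, and are scored for evidential strength; the
  literature object.

# From evidence to structure

## Independence queries and d-separation

The atomic measurable statement is the independence query
`A ⊥ B | C || J`: is `A` independent of `B` given the conditioning set
`C`, under interventions on the set `J`? An intervention is modelled by
graph surgery (the do-operator): every edge into an intervened variable
is deleted, because forcing a variable's value disconnects it from its
natural causes. After surgery, the graph's answer to the query is read
off by d-separation: a path is blocked where it passes a conditioned
chain or fork node, or a collider that is neither conditioned nor has a
conditioned descendant; independence holds iff every path is blocked.
`d_separated()` implements the linear-time reachability form of the
criterion; the test suite validates it against an exhaustive
path-enumeration oracle on every DAG with up to four nodes.

Two assumptions underlie the reading: the causal Markov condition (every
variable is independent of its non-effects given its direct causes) and
faithfulness (the distribution exhibits exactly the independencies the
graph implies). Both are assumed, not tested, throughout.

## Equivalence classes

Different graphs can answer every available query identically; such
graphs form a (Markov) equivalence class and no amount of data from
those settings can separate them. The package makes the class concrete:
`enumerate_graphs()` materializes the full graph space (25 DAGs on three
variables, 543 on four), and `equivalence_class()` keeps the members
whose independence signature matches a reference. The space is
super-exponential — 3,781,503 labeled DAGs on six variables, counted by
Robinson's recurrence in `count_dags()`, and `2^30` digraphs when
feedback is allowed — so materialization is capped (six variables
acyclic, five cyclic, overridable) and counts above the cap are analytic
only.

## Research maps, scores, and constraints

A research-map edge records *how* a causal claim was established: up to
four experiment kinds (positive/negative intervention `↑`/`↓`,
positive/negative non-intervention `∅↑`/`∅↓`) with repetition counts.
Two integration principles govern evidential strength: **consistency**
(repetition with the same result) and **convergence** (agreement across
different experiment kinds). The published ResearchMaps score is not
public, so `score_edge()` uses a clearly labelled surrogate,

$$s = (1 - 2^{-r}) \cdot k/4,$$

with `r` the total repetitions and `k` the number of distinct kinds
(1–4). It is the simplest form that is strictly increasing in both
arguments, lies in `[0, 1)`, and saturates at `k/4`: only full
methodological convergence can approach 1. The scorer is a pluggable
strategy (`scorer` argument) precisely because it is a surrogate.
Whether intervention kinds should weigh more than non-intervention kinds
is unstated in the source framework; the surrogate treats the four kinds
symmetrically. Records conflicting with an edge's majority relation are
dropped from `r` and `k` with a warning, keeping one relation per edge;
ties favour the edge's declared relation.

`translate_edge()` turns evidence into weighted constraints on
structure: an edge `A → T` backed by intervention records asserts
`A ⊥̸ T | ∅ || {A}`; non-intervention records assert the observational
`A ⊥̸ T | ∅ || ∅`; no-connection edges assert the corresponding
independence, under the same `J` as the recorded experiments (a
no-connection edge tested only under intervention does not claim
observational independence). The excitatory/inhibitory sign is
**deliberately dropped** — the constraint grammar has no sign slot, so
both signs assert dependence, and positive and negative interventions
translate identically. Edge scores become the constraint weights.
Hypothetical edges carry no evidence and are skipped by default; an
option maps them to `ε = 0.01`-weight constraints so stated hypotheses
can softly steer the optimization without masquerading as data.

`optimize_graphs()` is exhaustive weighted maximum-satisfiability: every
graph in the space is scored by the summed weight of violated
constraints and all minimizers are kept (no arbitrary tie-break). At
desk scale exhaustive search is exact and transparent; a clause-encoded
solver would only matter beyond the enumeration caps and is out of
scope. `forward_infer()` then recovers the full equivalence class of the
optimum; when several optima disagree on their signatures the union of
their classes is returned with the signature count attached.

# Quantifying what remains unknown

Three metrics grade a class's underdetermination:

* **count** — the number of member graphs;
* **degrees of freedom** — each pair of variables is in one of four edge
  relations (none, forward, backward, both), so a pair still exhibiting
  `m` relations across the class contributes `m − 1` undetermined
  instantiations; the maximum is `3·C(n,2)`;
* **edge entropy** — the base-2 Shannon entropy of the empirical
  relation fractions across members, per pair; 0 bits when determined,
  2 bits at uniform over the four relations.

The base is fixed at 2 because the worked three-graph example
(`−(1/3)log(1/3) − (2/3)log(2/3) ≈ 0.918`) only reproduces in bits.
`0·log 0` is taken as 0 (only nonzero terms enter). The class-level
entropy is reported both as the sum and the mean over pairs; the sum is
the default planning key because it preserves scale as classes shrink.
Fully determined pairs count toward the mean's denominator — the mean is
over all pairs of the system, not over uncertain pairs. These are
empirical class fractions, not posteriors: no prior over graphs is
implied.

```{r}
chain <- causal_graph(c("X", "Y", "Z"), rbind(c("X", "Y"), c("Y", "Z")))
cls <- equivalence_class(chain)
uncertainty_report(cls)
```

# Ranking experiments

## On an equivalence class

A candidate experiment measures one query; its possible outcomes
partition the class (`possible_outcomes()`), and `information_gain()`
compares the current uncertainty with the outcome-weighted (or, in
`worst_case` mode, the maximal) posterior uncertainty.

`rank_experiments()` orders candidates by **two keys**: first the
current uncertainty of the pair the experiment tests (its edge entropy,
or its undetermined-relation count under the `dof` metric), then the
partition-based information gain, then lexicographic tie-break. The
two-key design is a deliberate resolution of a genuine tension: on the
three-graph chain class, *every* single-variable intervention — including
one testing the already-settled pair (X, Z), e.g. intervening on X and
measuring Z — splits the class 1:2 and carries the same expected gain
(≈1.170 bits), because resolving any one chain link resolves the whole
chain. Partition gain alone therefore cannot express the natural
prioritization "test the undetermined pairs first", while pair
uncertainty alone cannot express "an intervention beats an observation
whose outcome the class already fixes". The primary key encodes the
first judgement, the secondary key the second. For the `count` metric,
which has no per-pair analogue, information gain is the only key.

Positive and negative variants of a kind measure the same query, so the
default candidate grammar (`candidate_experiments()`) emits one
interventional candidate per ordered pair and one observational
candidate per unordered pair; the positive/negative distinction matters
only for research-map evidence bookkeeping. Conditioning sets up to size
one can be added by flag.

## On a research map

Four rules rank experiments by the evidence they would add:

* **pioneering** (`pioneering_candidates()`): pairs spanned by a
  directed path of length ≥ 2 through excitatory/inhibitory edges —
  hypothetical edges included, since hypotheses exist precisely to stage
  such tests — with no direct empirical edge; no-connection edges never
  extend a path;
* **weakest link** (`weakest_link()`): the empirical edge with the
  lowest score gets the next experiment;
* **single-edge convergence/consistency**
  (`suggest_experiment_kinds()`): absent kinds first, then present kinds
  by ascending repetitions;
* **multi-edge convergence** (`multi_edge_convergence()`): among
  equally attractive kinds, the one least represented across the whole
  map.

The framework does not state whether a pioneering candidate outranks a
weakest-link refinement when both apply, so the package reports both
lists side by side (see the CLI `plan` subcommand) rather than imposing
a cross-rule priority.

# The simulator and what a green test establishes

`run_loop()` closes the loop on synthetic ground truths: sample a truth
(`random_graph()`; acyclic sampling draws a variable order, then
includes each order-respecting pair with probability `edge_density`),
start from its full observational equivalence class, and repeatedly rank
candidates, perform the top one on an exact oracle (`oracle_outcome()`),
and refine the class. Defaults state the world of the worked examples:
three variables, density 0.5 (every DAG equally plausible as a truth,
in expectation), budget equal to the number of interventional
candidates, `entropy_greedy` policy.

The oracle is exact by design: outcomes are the constraint the truth
implies, with no finite-sample noise, matching the constraint-level
abstraction of the whole framework. A green simulation therefore
establishes the *logic* of planning — soundness (the truth never leaves
the class), monotone uncertainty reduction, greedy identification of
every three-node chain within three experiments, and a greedy-vs-random
advantage — but says nothing about statistical independence testing on
finite data, unfaithful distributions, latent confounders, or selection
bias, none of which are modelled.

# Numerical and degenerate-input choices

* Enumeration order is lexicographic in the row-major adjacency
  encoding; all streams and trajectories are reproducible, and every
  random choice flows from the config seed.
* Optimizer ties are resolved by *keeping* all optima; cost comparisons
  use an absolute `1e-12` tolerance on summed weights.
* Queries canonicalize their endpoint pair lexicographically, making
  signatures symmetric in (a, b) by construction.
* Cyclic graphs are enumerable and scoreable; independencies on them are
  read by the same trail criterion after surgery. **This is an
  approximation**: d-separation is not generally sound for cyclic
  models (sigma-separation would be, and is out of scope), so
  equivalence classes default to the acyclic space and the cyclic space
  must be requested explicitly.
* An empty intervention set leaves the graph untouched; an empty
  constraint list makes every graph optimal at cost 0; a singleton class
  has entropy 0, dof 0, and all experiment gains 0.

# Known limitations

The package does not model effect sizes, structural equations, latent
variables, or noisy independence tests; the evidence score is a
surrogate, not the published ResearchMaps calculation; exhaustive
enumeration limits exact optimization to the stated caps; and cyclic
independence semantics are approximate as described above. Node
identity is a plain string (with an opaque `ontology_id` passthrough),
so cross-map phenomenon reconciliation is the user's responsibility.
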