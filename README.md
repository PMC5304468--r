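# causalplanr

Experiment planning toward causal discovery, for systems at the scale a
scientist actually reasons about (three to five phenomena: a pathway
fragment, a signalling cascade, a behavioural circuit). The package
answers two questions: given the published findings, **what does the
evidence still leave undetermined** about the causal structure of a
system, and **which experiment should be performed next** — the one that
most reduces that indeterminacy, or the one that would add the most
evidence.

## What it computes

**Structure from evidence.** Findings are represented as *research
maps*: evidence graphs whose directed edges are typed excitatory,
inhibitory, or no-connection, annotated with the experiment records that
support them (positive/negative interventions ↑/↓, positive/negative
non-interventions ∅↑/∅↓, with repetition counts) and scored in [0, 1)
by a surrogate of the consistency/convergence integration principles,
s = (1 − 2⁻ʳ)·k/4 for r total repetitions over k distinct experiment
kinds. Each edge translates into a weighted causal-structure constraint
A ⊥̸ T | C || J (interventional records give J = {A}, non-interventional
J = ∅; no-connection edges assert the independence instead; the edge
score is the weight). An exhaustive weighted max-satisfiability search
over all graphs of the space returns every graph minimizing the summed
weight of violated constraints, and forward inference expands the optima
into the full *equivalence class* — all graphs answering the available
independence queries identically, decided by d-separation after
intervention surgery (deleting the edges into intervened variables).

**Uncertainty of a class.** Three metrics: the graph count; the degrees
of freedom (each variable pair is in one of four edge relations — none,
→, ←, ⇄ — and a pair still exhibiting m of them across the class
contributes m − 1, out of a maximum 3·C(n,2)); and the per-pair edge
entropy H(X,Y) = −Σ P(rel)·log₂ P(rel) over the empirical relation
fractions, summed or averaged over pairs for a class-level figure.

**Experiment ranking.** Candidates (one interventional query per ordered
pair, one observational per unordered pair) are ranked by the current
uncertainty of the pair they test, then by the expected (or worst-case)
information gain of their outcome partition. Research-map rules —
pioneering spans, weakest link, single-edge convergence/consistency,
multi-edge convergence — rank experiments by the evidence they would
add. A closed-loop simulator replays the whole cycle against synthetic
ground truths with an exact oracle.

## Worked example

The chain X → Y → Z, observed without interventions:

```r
library(causalplanr)
chain <- causal_graph(c("X", "Y", "Z"), rbind(c("X", "Y"), c("Y", "Z")))
cls <- equivalence_class(chain)
uncertainty_report(cls)
#> uncertainty report: 3 graph(s)
#>   degrees of freedom: 2 (22.2% of maximum)
#>   H(X--Y) = 0.918 bits
#>   H(X--Z) = 0.000 bits
#>   H(Y--Z) = 0.918 bits
#>   class entropy: sum 1.837, mean 0.612 bits
```

Purely observational data cannot orient the chain: three graphs
(X → Y → Z, X ← Y → Z, X ← Y ← Z) answer every observational query
identically. Both adjacent pairs are maximally torn between their two
observed orientations (1/3 vs 2/3, 0.918 bits each); the (X, Z) pair is
settled (no member has the edge, 0 bits). Ranking the nine default
candidate experiments:

```r
head(as.data.frame(rank_experiments(cls, metric = "entropy_sum")), 4)
#>   agent target    kind pair_uncertainty info_gain posterior_sizes
#> 1     X      Y pos_int        0.9182958  1.169925             1|2
#> 2     Y      X pos_int        0.9182958  1.169925             2|1
#> 3     Y      Z pos_int        0.9182958  1.169925             2|1
#> 4     Z      Y pos_int        0.9182958  1.169925             1|2
```

Interventions on the undetermined pairs lead: each splits the class 1:2
and is expected to remove 1.170 of the 1.837 bits. Every (X, Z)
experiment ranks below every (X, Y) and (Y, Z) experiment. On the
evidence side, with the X → Y edge scored 0.250 and Y → Z scored 0.125:

```r
map <- research_map(c("X", "Y", "Z"), list(
  rm_edge("X", "Y", "excitatory",
          list(experiment_record("pos_int", "excitatory", 1)), score = 0.250),
  rm_edge("Y", "Z", "excitatory",
          list(experiment_record("pos_int", "excitatory", 1)), score = 0.125)
))
wl <- weakest_link(map)
#> weakest link: Y -> Z (score 0.125)
pioneering_candidates(map)
#>   agent target
#> 1     X      Z
```

— the least-supported link gets the next experiment, and the spanning
connection X → Z, implied by the path but never tested directly, is
flagged as a pioneering candidate.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

rebuilds the three-graph equivalence class of the chain from scratch
(enumerating all 25 three-node DAGs and filtering by observational
signature) and reports the edge-relation entropies of the (X, Y) and
(Y, Z) pairs, in bits, as JSON.
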