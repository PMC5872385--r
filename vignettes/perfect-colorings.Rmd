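---
title: "Perfect colorings of signed regulatory graphs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Perfect colorings of signed regulatory graphs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(percolor)
```

## The model

An influence graph carries molecular species as nodes and signed, weighted
directed edges: `+1` for activation, `-1` for inhibition. Between two
cellular conditions each species shifts qualitatively `up` or `down`; a
*coloring* is a total assignment of these signs. The local rule is the
classic sign-consistency one: a predecessor *explains* a target when an
activation edge carries the same sign on both ends, or an inhibition edge
carries opposite signs.

Rather than demanding a fully consistent labeling — rarely attainable on
curated pathway graphs — the method ranks colorings by a lexicographic
objective: first the number of *inconsistent* targets (explained by no
predecessor), then the number of *imperfect* targets (failed by at least one
predecessor), then the summed weight of the failing (*imperfect*) regulators.
The intuition is redundancy of biological control: a target's state should
be explained by as many of its regulators as possible. All colorings
attaining the lexicographic minimum — the *perfect colorings* — are
enumerated **completely**; downstream correlation analysis depends on having
the whole set, not a single witness, so both solver backends collect every
optimum.

Assumptions worth stating explicitly:

- two-state (up/down) abstraction; no neutral state, no kinetics;
- every edge is independently explanatory (no AND-gates between regulators);
- the rules are sign-symmetric, so the unfixed optimum set is closed under
  the global flip of all colors: solutions come in mutually-reversed pairs;
- self-loops have no defined semantics and are rejected before analysis;
- only nodes with predecessors are constrained; predecessor-free nodes are
  free variables (an isolated node doubles the model count).

## Solution-space reduction

Enumerating `2^n` colorings directly is hopeless for realistic graphs, so
the graph is first compressed by three reductions that merge nodes whose
colors are provably correlated in every optimum, recording each member's
relative sign to its subcomponent:

1. **consistency** — a node with a single predecessor and single incoming
   edge copies (activation) or flips (inhibition) that predecessor's color
   in every optimum; it is absorbed with relative sign equal to the edge
   sign, iterated to fixpoint;
2. **co-regulators** — two predecessor-free nodes whose single out-edges
   point at the same successor must both explain it in any optimum (failing
   one could be flipped for free, strictly improving the objective), so the
   pair merges with relative sign equal to the product of their edge signs;
   mixed-sign pairs merge with relative sign `-1` (a strict same-sign-only
   mode is available);
3. **edge balance** — between two subcomponents, same-sign edge weights are
   summed; an opposite-sign pair `(w1, w2)` leaves a single residual edge of
   weight `|w1 - w2|` while the target is flagged *always consistent and
   always imperfect* with residual weight `min(w1, w2)`: whatever the
   colors, exactly one of the two original edges explains the target and one
   fails. Fully cancelled subcomponents become isolated, color-independent
   components of their own.

By default the reductions run once each, in that order — consistency to
fixpoint, then co-regulators to fixpoint, then balance — which reproduces the
step-by-step narrative on the shipped toy graph. A co-regulator merge can
expose a fresh single-predecessor pattern (the merged pair's summed edge);
`interleave = TRUE` chases those to the joint fixpoint and
`rerun_after_balance = TRUE` re-enters the loop after balance deletions. All
variants preserve the optimum; the default is chosen so intermediate objects
match the canonical worked example, and the final component decomposition is
identical either way because correlation analysis picks up whatever the
extra merges would have.

### Validity guards

The merge patterns as stated are only sound when the optimum has the
structure they presume; three guards make the implementation exact on
arbitrary graphs, verified against exhaustive enumeration:

- **negative cycles**: a cycle with negative sign product forces at least
  one inconsistency, and the optima may place the failing edge anywhere
  tied-cheapest on the cycle — including across a would-be merge. A
  consistency merge across an edge lying on any negative cycle (checked by
  sign-parity reachability) is refused, leaving such cycles explicit for the
  enumerator.
- **positive cycles**: collapsing a positive cycle produces an internal
  self-activation that is satisfied in every coloring. The loop edge is
  dropped but the subcomponent is marked *always consistent*, so its entry
  member can never be counted inconsistent — dropping the mark silently
  would misscore colorings that break the subcomponent's remaining external
  edge.
- **no upstream absorption of self-explained targets**: a subcomponent
  marked always-consistent, or flagged by edge balance, can decouple from
  its remaining predecessor at imperfection cost only; that cost can tie
  with other optima, so such nodes are never absorbed into their
  predecessor even when the single-edge pattern matches.

With the guards in place, enumerating the reduced graph and expanding
through the relative signs reproduces the full graph's optimal model set and
objective exactly; the test suite asserts this equality on randomized
corpora (200 graphs of up to 12 nodes, mixed densities, sign ratios and
weights) against brute-force `2^n` enumeration, for every reduction variant.

Because a reduced graph may carry flags, its objective bookkeeping deserves
one note: a flagged target contributes its stored residual weight to the
third objective in every coloring (so reduced and original graphs report
identical objectives), and a flagged target that loses all its edges
contributes a constant `(0, 1, residual)` that is added back outside the
enumeration.

## Enumeration backends

- `bruteforce` vectorizes the scan of all `2^n` colorings (refused above a
  configurable cap, default 20 nodes);
- `branchbound` (default) does depth-first search over node assignments
  with a lexicographic lower bound from fully-decided targets, collecting
  all ties — exact and usually much faster than the scan;
- `asp` grounds an ASP-Core-2 encoding (`emit_asp_program()`: choice rule,
  consistency/imperfection definitions and three `#minimize` statements at
  priorities 3 > 2 > 1) with an external `clingo` solver when one is on the
  PATH, and errors loudly otherwise — never a silent fallback.

Weight arithmetic is integer-scaled (6 decimal places) internally so that
lexicographic comparisons never hit floating-point ties. Model sets are
ordered canonically (lexicographically by the concatenated node signs) and
carry no tie-breaking beyond that: the result is a set.

Fixing one node's color halves the search space; by symmetry the full set is
recovered afterwards by `flip_complete()`. `perfect_coloring()` does this
automatically (smallest node of the largest connected reduced part, fixed
`down`) and restores the closure before any correlation, so fixing is purely
an optimization and never changes results.

## Components

Across the enumerated optima, each unordered node pair is counted colored
alike (`a`) or opposite (`b`): `b = 0` is positive correlation, `a = 0`
negative, both non-zero independent. Self-pairs are excluded. Positive and
negative relations are transitively closed into *components* (with a
coherence assertion along closure paths), isolated subcomponents from edge
balance join as their own components, and free nodes fall out as singletons
automatically. Correlation is always computed over the complete model set —
over a sample the relation would not be transitive. Each component carries
two mutually-reversed configurations; `config1` canonically assigns `up` to
the lexicographically smallest member.

## Expression scoring

Profiles are discretized per sample against the mean of the designated
control samples: `up` at or above `fold` times the control mean, `down` at
or below the control mean divided by `fold`, unobserved inside the band. The
default `fold = 1.2` is the package's calibration for fold-change
discretization of expression arrays; both boundaries are inclusive so the
discretizer is monotone in the measured value, and comparisons are on the
raw scale (a `log2_scale` mode shifts by `log2(fold)` instead). Control
means must be positive on the raw scale; offending genes are skipped with a
warning. Gene-to-node mapping is by exact identifier: aliasing between probe
ids, gene symbols and graph nodes is the caller's explicit responsibility.

The maximal similarity of a component against a profile restricted to its
members is `MS = max(k, n - k)/n`, `k` counting agreements with `config1`.
Since the two configurations are exact reverses, agreements partition the
`n` observations, bounding MS in `[1/2, 1]`; it is undefined (`NA`) when no
member is observed.

## Validation

For each component, MS over the real profiles is compared with MS over
`n_random = 5` sign-scrambled copies of every profile (labels permuted
within each profile independently; observed node set and up/down counts
conserved exactly), pooled into one comparison sample, using Welch's
unequal-variance two-sided t-test. With case/control groups, a second Welch
test contrasts group MS distributions (*specificity*). The 0.05 threshold is
a reporting convention, not logic. Note that scrambling is uninformative for
a component whose configuration is all-up or all-down — permuting identical
labels changes nothing — so validation is meaningful only for mixed-sign
configurations; the test fixtures use alternating-sign chains for exactly
this reason. All randomness flows from one root seed and reruns are
byte-identical.

## Cluster-quality metrics

To compare a component decomposition with other graph clusterings on
enrichment output, `se_index()` scores a cluster as the fraction of its
enriched ontology terms lying strictly deeper than a threshold in the term
DAG (minimal depth from the root, breadth-first), and `clustering_quality()`
sums `SE * n_genes` over clusters. The default threshold 7.07 is the mean
minimal depth of the ontology snapshot used when the metric was calibrated;
recompute it from your own snapshot (`mean(term_depths(dag, root))`) rather
than trusting the default, and choose explicitly which relations (`is_a`
alone or with `part_of`) define the DAG you supply. Enrichment itself
(hypergeometric testing against an ontology service) is out of scope:
enrichment tables are inputs.

## Synthetic data

`random_signed_graph()` draws simple directed graphs (no self-loops,
uniform edges, Bernoulli inhibition signs, integer weights) as
property-test corpora. `synthetic_profiles()` emulates the discrete
observation model: each member of a component is observed with probability
`1 - unobserved_rate` and its configured sign is flipped independently with
probability `epsilon` — sign-flip noise on the discretized scale, not
Gaussian expression noise. Both are pure functions of their seeds.

What the generator does *not* emulate about real data: correlated noise
across genes, probe-level intensity distributions, uneven coverage of the
graph by measurable transcripts, and the transcriptional-versus-
post-translational distinction (observations attach to whatever node ids
you map them to). Passing recovery tests therefore demonstrates the
statistic's behavior under its own observation model, not performance on any
particular platform.

## Problem sizes and numerical choices in the test suite

The suites run exhaustive oracles where exhaustion is feasible: corpora of
200 random graphs up to 12 nodes for backend equivalence and reduction
soundness; a 100-node alternating chain with 200 profiles at flip noise 0.1
for recovery (mean MS within three standard errors of 0.9); 300–400
simulation repetitions for null calibration of the specificity test
(rejection rate within three binomial standard errors of 0.05); and the
exact binomial value of `E[max(B, m - B)]/m` as the reference at maximal
noise. These sizes are the package's chosen study conditions; they keep the
oracles exact while exercising every code path.

## Limitations

- Exhaustive enumeration is exponential: both exact backends are meant for
  reduced graphs of a few dozen constrained nodes at most. Larger graphs
  need the ASP backend with an external solver.
- The model-set and component contracts require *complete* enumeration;
  there is no approximate or sampled mode in the tested surface.
- The reduction guards are conservative: on densely cyclic graphs little
  may be merged, shifting all the work to the enumerator.
- The two-state abstraction cannot express "unchanged"; genes inside the
  discretization band are simply unobserved.
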