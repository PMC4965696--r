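---
title: "Module-cover pathway extraction: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module-cover pathway extraction: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modulecover)
```

## The model

The input is an undirected interaction network $G(V, E)$ over gene
identifiers and a binary indicator matrix with genes as rows and cases
(samples) as columns; entry 1 means the gene is "active" in that case —
what counts as active is up to the upstream analysis (a differential
expression call, a variant, a thresholded p-value via
`pvalues_to_indicator()`, which uses a *strict* $p < \text{cutoff}$
rule). The module-cover objective is to find maximal *connected*
subnetworks whose genes cover as many active cases as possible, governed
by two parameters:

* $L$ — **case exceptions**. A gene's *exception count* is its number of
  inactive cases; under INES a gene is active when that count is at most
  $L$. $L$ may be given as an absolute count or as a percentage of the
  number of cases, which makes one setting portable across datasets with
  different case counts. Percentages resolve as
  $\lceil p/100 \cdot n\rceil$: the ceiling guarantees that "allow $p\%$
  exceptions" never rounds away an exception the user asked for
  (`resolve_l("20%", 38)` is 8).
* $K$ — **exception nodes** (INES only). Up to $K$ inactive genes may
  join a solution to bridge active regions. This is how a
  non-differentially-expressed hub whose neighbours all respond — the
  classic disease-gene signature — can enter the solution.

**INES** validity: the induced subgraph is connected and contains at most
$K$ inactive nodes. **GLONE** validity: connected, and the *sum* of
exception counts over all member genes is at most a single global budget
$L$; there is no per-node exception-node budget, which reduces the pull
of high-degree hubs at some run-time cost.

A note on one boundary: `resolve_l()` caps an *absolute* $L$ at the case
count, because more per-gene exceptions than cases is meaningless. The
GLONE budget, however, is a total across all solution genes and may
legitimately exceed the case count (a solution of $m$ genes can spend up
to $m \cdot n$ case exceptions), so GLONE resolves percentages the same
way but leaves absolute budgets uncapped — otherwise the sanity property
"GLONE with $L = n_{\text{cases}} \cdot |V|$ returns the whole connected
component" could not hold.

Datasets can be combined before extraction with a logic formula over
dataset ids (`AND`/`OR`, `AND` binding tighter, no negation), evaluated
case-by-case; genes missing from a dataset contribute all-zero rows, so
`AND` is conservative. Only case-aligned combination (equal case counts)
is supported; a per-dataset-$L$ mode for unequal case counts is a known
limitation. Positive lists force genes to zero exceptions (always
active); negative lists delete genes from the network before extraction.

## Extraction algorithms

**Greedy.** One candidate is grown from every feasible seed (every
active node; under INES with $K \ge 1$ every node, since an inactive
seed spends budget). Growth repeatedly adds the feasible neighbour that
is (1) active first, then (2) adjacent to the most active nodes not yet
in the solution, then (3) smallest by identifier — a deterministic rule,
so results are reproducible without a seed. Growth stops when no
feasible neighbour remains; candidates are deduplicated and ranked by
size, ties broken by the lexicographically smallest sorted node tuple.
The expansion heuristic is this package's own design; rather than chase
bug-for-bug parity with any particular historic implementation, it is
validated against the exact optimum on hundreds of random small
instances in the test suite.

**Exact.** For instances up to 15 nodes, `exact_extract()` enumerates
every connected induced subgraph exactly once (grow-from-each-root
enumeration with an exclusion set) and returns a maximum-cardinality
feasible solution. Both INES and GLONE costs are monotone under growth,
so any branch that exceeds its budget is pruned wholesale. The same
optimum is recomputed in the tests by an entirely independent bitmask
subset enumeration; the two must agree, and the greedy solution may
never exceed them.

**Border-exception-node (BEN) filter.** With a generous $K$, exception
nodes are often appended at the periphery merely to inflate solution
size, producing near-duplicate top solutions. The filter repeatedly pops
a random node $v$ from the solution's exception set; components of the
solution minus $v$ consisting solely of exception nodes are marked, and
if exactly one component contains a non-exception node, $v$ itself is a
border exception node and is marked too; marked nodes are removed and
the loop continues until the exception set is exhausted. All active
(non-exception) genes are always retained, connectivity is preserved,
and re-applying the filter changes nothing. Which *exception* nodes are
retained can in principle depend on the pop order, so the order is
seeded and the seed exposed (`rng_seed`); the retained non-exception set
is order-invariant, which the tests check across seeds.

## Perturbation semantics

The perturbation level is a percentage in $[0, 100]$; since the source
model leaves the mapping from "degree of perturbation" to operation
counts implicit, this package declares one: the level is the fraction of
*nodes* relabelled or removed, and of *edges* rewired or removed, with
round-half-up counts. Rewiring counts *edges rewired* (each successful
Maslov–Sneppen swap rewires two edges, and a rewired edge is marked so
it is not counted twice), keeping levels comparable across strategies.
Swaps that would create self-loops or duplicate edges are rejected, and
the sampler gives up with a warning after $100\times$ the target count
of attempts — some graphs (a star, for example) admit no valid swap at
all. Indicator matrices are deliberately *not* relabelled under label
permutation: activity follows the gene label while its topological
position changes, which is precisely the disruption the strategy is
meant to probe.

Every strategy is bit-reproducible for a fixed seed. Batch analyses
derive one seed per (strategy, level, replicate) by hashing those labels
together with the master seed, so adding a level or switching strategies
never shifts the random stream of other replicates.

## Robustness and validation analyses

`robustness_analysis()` extracts once from the unperturbed network, then
per level and replicate perturbs, re-extracts with identical settings,
and records the Jaccard overlap between the *largest* solutions (most
nodes; lexicographic tie-break). `validation_analysis()` records overlap
with a user-supplied gold-standard set instead, plus the unperturbed
baseline. Failed replicate extractions are recorded as empty solutions
rather than aborting a batch. Two conventions: the Jaccard of two empty
sets is 1 (they are equal; a warning is logged), of an empty versus a
non-empty set 0; and gold comparisons use *all* genes of a solution
including exception nodes, since finding a known disease gene as an
exception node is a success, not noise. Summaries are descriptive
(mean, sd, median, min, max per level); no significance testing is
attempted on the curves.

## The synthetic benchmark

`generate_synthetic_instance()` emulates the qualitative structure of
real inputs: a scale-free background network (preferential attachment —
biological interaction networks are approximately scale-free, which is
also why moderate random perturbation leaves hubs, and hence solutions,
largely intact), with a planted connected module grown by randomised BFS
from a random root. Matrix entries are independent Bernoulli draws:
module genes active with probability 0.95 per case, background genes
0.05, over 40 cases by default — a strong, clean signal. The default
instance (100 nodes, attachment 2, module 10) is the package's standard
benchmark condition: with INES, greedy, $K = 2$, $L = 20\%$, the planted
module is recovered with Jaccard $\ge 0.8$ (the extractor typically
finds all 10 planted genes plus its 2 permitted exception bridges,
giving $10/12 \approx 0.83$).

What the generator does *not* emulate: correlated activity across genes
or cases, batch effects, degree-biased measurement coverage, missing
rows, or realistic network noise. Passing the planted-module tests
therefore demonstrates correctness of the machinery under a known
ground truth, not performance on real cohorts.

Problem sizes used in the automated checks were chosen to keep the full
suite comfortably interactive: oracle comparisons use 200 random
connected graphs of 4–10 nodes and up to 4 cases; the BEN filter is
verified on every connected labelled graph of up to 4 nodes and sampled
5–6-node graphs, under every exception labelling; batch analyses use the
100-node benchmark with 10 replicates per level.

## Numerical and degenerate-input choices

* Self-loops are dropped (with a warning) and duplicate edges collapsed
  at read time; the model is blind to direction and multiplicity.
* An indicator file's first row is a header iff any non-gene field is
  not `0`/`1` *and* data rows follow; a lone non-binary row is an error,
  not a header.
* Ties are broken everywhere by sorted node-identifier tuples, never by
  memory order, so every ranking is stable across platforms.
* Empty networks, empty solution lists, all-zero matrices and
  level-0/level-100 perturbations are all defined and tested rather than
  left as edge cases.

## Limitations

Beyond the synthetic-data caveats above: no ant-colony or
fixed-parameter-tractable search (the exact enumerator is intentionally
restricted to small instances and used as an oracle); no identifier
mapping between annotation namespaces; undirected, unweighted networks
only; dataset combination requires aligned case counts.
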