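---
title: "Counting signed causal paths for drug prioritization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting signed causal paths for drug prioritization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(causalpaths)
library(dplyr)
```

## The model

`causalpaths` works on a directed graph `G = (V, E)` whose edges carry a
polarity in `{+1, -1}`: activation or inhibition. The effect of a path is
the product of its edge polarities, so each path from a source `s` (a
drug) to a target `t` (an indication or phenotype) is either activatory
or inhibitory. Writing `A` and `I` for the two path classes up to a
maximum length `lmax`, the relative effect
`delta = |I| / (|A| + |I|)` (for the inhibition direction) estimates how
consistently the network's causal wiring predicts that perturbing `s`
reverses `t`. The complementary normalized score
`(|A| - |I|) / (|A| + |I|)` lives in `[-1, 1]`; a pair with no paths at
all is a *distinct* state (`NA` in all outputs), never conflated with the
cancelling score 0.

Two assumptions are worth making explicit. First, all paths are treated
as equally credible: no edge weights, kinetics, or confidence scores —
the prediction is a vote over the path ensemble, which is exactly why
consistency across a *range* of `lmax` is demanded downstream. Second,
association-type edges (protein–indication, protein–phenotype) typically
lack causal annotation in source databases and are conventionally
inferred as activations; the polarity vocabulary makes that inference
explicit and configurable (`default_vocabulary(default_association =
FALSE)` turns it off, making unmapped labels an error).

## The two counting variants

**Walks (`variant = "all"`).** The number of paths from `s` to `t` within
`k` steps decomposes over the neighbours of `s` with budget `k - 1`. The
engine evaluates this recurrence with one `(node, exact length)` state
per node and length, bottom-up (the iterative equivalent of top-down
memoization), tracking activatory and inhibitory counts as a pair.
Relaxing an inhibitory edge swaps the pair retrieved for the neighbour —
path effects compose by sign multiplication, so suffix counts can be
reused without storing any path. Consequences:

* at most `|V| * (lmax + 1)` states are ever evaluated, independent of
  how many walks are counted (the `"states"` attribute of
  `count_paths()` exposes the instrumentation; the test suite asserts
  the bound on every graph it touches);
* cycles are traversed naturally up to the length budget;
* the semantics are **target-absorbing**: the base case of the
  recurrence is the zero-length walk sitting at `t`, and `t` is never
  expanded, so a walk terminates at its *first* arrival at the target.
  Walks through `t` and back are not counted. The brute-force oracle in
  the test suite implements the same rule independently.

The degenerate query `s == t` returns one activatory path (the empty
product is `+1`), which is the recurrence's base case; drug–disease
applications use `lmax >= 2` and distinct endpoints so that at least one
intermediate node is involved.

**Simple paths (`variant = "simple"`).** Cycle-free counting cannot reuse
suffix counts across branches (a cached count is valid only for a
specific visited set), so it runs as a depth-first search with an
explicit visited set and two prunings: the remaining-length budget, and a
reverse-BFS table of distances to the target that abandons a branch as
soon as `t` is provably out of reach. Worst-case cost is exponential in
`lmax` — inherent to the problem — but the distance pruning makes the
search practical on sparse biological networks; the acceptance suite
measures it an order of magnitude faster than naive enumeration on a
2,000-node network.

Counts are stored as R doubles, which hold exact integers up to 2^53 —
comfortably beyond the millions of paths that realistic networks reach at
`lmax = 8`; the engine warns if a count ever exceeds that range.

## Prioritization criteria

A pair is prioritized when three criteria hold over an `lmax` range
(default `2:8`, chosen to span from the shortest biologically meaningful
drug–target–disease chain to long signalling cascades, beyond which
scores tend to converge as contradictory interactions cancel):

1. **High effect**: `delta >= threshold` (default `0.75`) at at least
   `quota` of the `lmax` values (default all seven; `quota = 6` is the
   common relaxation).
2. **Support**: paths must exist at every `lmax` counted toward the
   quota. An `lmax` with no paths fails criterion 1 there as well — no
   paths is no evidence, a deliberate design choice.
3. **Growth**: the path total strictly increases at every consecutive
   step, so the verdict is not driven by a single short path.

Within the prioritized list, ranking is by mean `delta` over the range
(descending), ties by total paths at the largest `lmax` (descending),
then lexicographic pair id — a deterministic order where the method
itself specifies none.

A subtlety in per-`lmax` bookkeeping: the cumulative activatory and
inhibitory counts are each non-decreasing in `lmax`, which constrains
what (total, fraction) sequences are jointly realizable on an actual
graph. Illustrative tables of per-`lmax` counts and inhibitory
percentages are therefore interpreted *per exact length* by
`fixture_for_profile()`, the only reading under which any requested
integer-valued sequence is realizable; `lmax_sweep()` exposes the
matching per-length breakdown (`step_activatory`, `step_inhibitory`)
alongside the cumulative counts it reports by default. For
`prioritize_pairs()` the distinction is immaterial — it consumes
whatever per-`lmax` `total`/`delta` columns it is given.

Percentages in display strings are truncated, not rounded, to two
decimals (e.g. 3.1986% prints as "3.19"), matching the convention of the
validation tables this package's outputs are meant to sit next to; raw
ratios are always reported alongside.

## Multi-target and combination scoring

`multi_target_profile()` scores one drug against each member of a target
set independently; a drug that cannot reach a phenotype gets the no-path
state for that entry without affecting the others.
`rank_multi_target()` orders drugs by how many targets they affect in
the desired direction, then by mean absolute normalized score.

For combinations, the aggregate counts of a drug set are the *sums* of
the per-drug counts. This is a design choice the underlying method
leaves open; it is the unique aggregation that degenerates to the
single-drug case for singletons, is order-independent, and coincides
with a virtual super-source construction (a node wired by `+1` edges to
every member drug, queried at `lmax + 1` with absorbing semantics) — the
test suite asserts that equivalence on random graphs. It follows that a
combination's `delta` is a totals-weighted average of its members', so
it always lies between their minimum and maximum. Callers who prefer the
stricter semantics — every member drug individually passing the
threshold — set `require_each = TRUE` in `enumerate_combinations()`.
Paths are deliberately not deduplicated across member drugs: two drugs
converging on the same intermediate protein contribute two paths, which
is the intended signal of a convergent mechanism, not double counting.

## Permutation null

`xswap_permute()` randomizes the network while preserving each node's
in-degree and out-degree and the global polarity counts: repeated swaps
`a -> b, c -> d  =>  a -> d, c -> b`, rejecting proposals that would
create self-loops or duplicate `(from, to, polarity)` edges. Two choices
strengthen the null beyond the minimal contract:

* polarity and relation travel with the *source* endpoint, so each
  node's signed out-degree is preserved exactly, not just the global
  sign counts;
* when modalities are annotated, swaps are proposed only within a
  relation layer (drug→protein edges swap with drug→protein edges,
  etc.), so the permuted network is still a structurally valid
  multimodal graph.

The default budget of `10 * |E|` swap attempts follows common practice
for degree-preserving randomization; swap rejection makes the realized
number of applied swaps smaller, which is logged in no way other than
the returned graph (rejections are part of the algorithm, not errors).

## The synthetic generator

`generate_network()` emulates the structure of curated multimodal
networks with exactly four relation layers: drug→protein binding,
protein→protein signalling (both signed, inhibitory with probability
`rho = 0.3` by default), and protein→indication / protein→phenotype
associations (always `+1`, the association-as-activation convention).
Default layer sizes (10 drugs, 100 proteins, 5 indications, 10
phenotypes) and densities (0.03 for the signed layers — mean out-degree
about 3, typical of curated signalling resources — and 0.05/0.03 for
associations) give a small but structurally faithful graph that the
whole test suite can sweep in milliseconds.

Planted mechanisms are layered amplifier gadgets: the planted drug sends
one inhibitory edge into a first layer of `width` reserved proteins,
successive layers are fully connected by activations, and every layer
projects onto the target, yielding `width^(k-1)` inhibitory paths of
every exact length `k = 2..depth`. With the defaults (`width = 2`,
`depth = 8`) a planted pair has `delta = 1` and strictly growing totals
at every `lmax`, i.e. it passes the prioritization criteria *by
construction* — the generator's contract. To make that guarantee
unconditional, planted drugs and gadget proteins emit no background
edges (they may still receive them). This shielding is an idealization:
real drugs have off-mechanism targets that dilute `delta` below 1, so
passing the planted-recovery tests demonstrates that the pipeline
recovers a clean signal and rejects its degree-preserving permutation —
not that it would tolerate arbitrary real-world noise. Features of real
networks the generator does not emulate: scale-free degree
distributions, correlated edge placement (hub proteins), contradictory
duplicate edges, and literature-bias artifacts.

`fixture_for_profile()` builds exact-count fixtures: for each requested
(length, count, inhibitory-count) it lays down vertex-disjoint layered
gadgets whose widths multiply to the requested count (an integer
factorization, so even counts in the thousands need only dozens of
nodes). The resulting graph is acyclic with disjoint gadgets, so the
walk and simple-path variants agree on it — which the tests exploit.
Infeasible requests (a non-integer inhibitory count such as 80% of 1
path, or more inhibitory than total) are errors.

## Numerical and degenerate-input choices

* Duplicate edges with identical `(from, to, polarity)` collapse to one
  (warned); opposite-polarity parallels are both kept and both counted —
  context-dependent regulation is biologically meaningful, and the
  engine handles the two edges as distinct paths. How the original
  curated networks resolved such contradictions is unknown; retaining
  both is this package's documented choice.
* Node ids are opaque strings, preserved verbatim; modality is optional
  metadata the engine never requires.
* Empty networks, disconnected pairs, and zero-swap permutations are
  all valid inputs with well-defined outputs (empty tibbles, no-path
  states, the identity).
* All randomness (generator, permutation) flows through explicit seeds
  via `withr::with_seed`, leaving the session RNG untouched;
  re-running any scenario with the same inputs reproduces result files
  byte for byte.

## Problem sizes in the shipped checks

The test and acceptance suites run entirely on generated data: oracle
equivalence on 200 random digraphs of 8–14 nodes at `lmax` 4–6 (sizes
at which exhaustive enumeration is itself trustworthy), planted-recovery
and permutation-null checks on 20 replicates of the default 125-node
generator, and a scalability trend on a 2,000-node, ~11,000-edge network
(walk counting at `lmax = 15` completes in well under a second; pruned
simple-path counting is measured against naive enumeration at
`lmax = 6`). These sizes were chosen so the full suite completes in
under a minute on one core while still exercising every code path at
meaningfully non-trivial scale.

## Known limitations

* The ensemble vote treats all paths equally; edge confidence, reaction
  kinetics and effect magnitudes are out of scope (they would enter as
  edge weights, which the counting recurrence does not currently carry).
* Simple-path counting remains exponential in `lmax` in the worst case;
  beyond `lmax ≈ 8` on dense networks, use the walk variant.
* The shortest-path baseline reports pairs whose *shortest* paths
  include the desired direction; when shortest paths disagree in sign
  the pair is flagged `mixed` rather than resolved — the underlying
  method defines no resolution.
* Identifier normalization across vocabularies (e.g. mapping DrugBank
  ids onto PubChem) is explicitly not provided; inputs must share a
  namespace.
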