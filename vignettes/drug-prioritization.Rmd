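---
title: "Network-based drug prioritization: models, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network-based drug prioritization: models, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netRx)
```

## The problem

A tumor sample carries a set of somatically altered genes (mutations and
copy-number alterations). An upstream driver-prioritization tool assigns
each altered gene a *driverness* score in [0, 1] — the probability that it
is a cancer driver. `netRx` turns those per-gene probabilities into a
per-drug ranking for that one sample, using only the topology of a protein
interaction network (PIN) and a drug–target interaction table. The premise
is that a drug is more promising the closer its targets sit to
high-driverness genes, with "close" read off the interaction network so
that indirect (pathway-level) relationships also count.

## The extended network

Interactions below a confidence cutoff (default 0.4, on the unit scale;
STRING-style integer scores 0–1000 are supported via
`dialect = "string1000"`) are discarded, self-loops and duplicate edges are
removed, and directionality is ignored throughout. Drugs are then added as
nodes wired to their in-network target genes. Two deliberate conventions:

* **Merging.** Drugs with *identical* target sets are indistinguishable to
  either scorer, so they are merged into a single node named by the sorted
  member names joined with `"/"`. A merge ledger preserves the original
  names so per-drug annotations (clinical tiers) can still be resolved;
  a merged drug takes the most clinically advanced member tier, since the
  merged node represents any member being prescribable.
* **Out-of-network targets.** A target gene absent from the PIN
  contributes no edge; a drug whose targets are all absent is kept as an
  isolated, flagged node. This keeps the scorers total over the input drug
  list — such drugs simply score 0 — rather than silently shrinking it.

Gene symbols are matched case-sensitively after whitespace trimming; no
alias resolution is attempted, so the PIN, drug table and driverness table
must share a symbol vocabulary.

## Distance-based scoring

For drug $d$ and altered gene $g$,

$$s_{d,g} = \frac{\mathrm{driver}_g}{(\mathrm{dist}(d,g)+1)^2},$$

where $\mathrm{dist}(d,g)$ is the unweighted hop count of the shortest
path from the drug to the gene. The $+1$ guards the division (a direct
target has distance 1, not 0, because the drug–target edge itself counts
as a hop) and the square makes contributions decay fast, emphasizing genes
near the drug's targets. Paths never pass *through* drug nodes:
drug–target edges are traversed only as the first hop, which the
implementation enforces by running a multi-source breadth-first search
over the gene-only graph and adding 1. Edge confidences filter the network
but are never used as path weights.

The drug score averages $s_{d,g}$ over the altered genes with driverness
*strictly above* 0.05 (`driver_threshold`; genes exactly at the cutoff are
excluded). Conventions at the boundaries:

* **Unreachable genes** contribute 0 to the sum but stay in the
  denominator — the natural limit of $1/(\mathrm{dist}+1)^2$ as the
  distance grows, and the only reading under which the mean is taken over
  the full altered-gene set.
* **Altered genes absent from the PIN** are excluded from numerator and
  denominator with a warning: they have no node, hence no distance.
* If *no* altered gene passes the filter, every drug scores 0 and the
  result carries an `empty_driver_set` flag rather than erroring — such
  all-quiet samples occur in practice and should flow through batch
  pipelines.

A consequence worth knowing: raising a gene's driverness while it stays
above the threshold can only raise drug scores, but pushing a gene *across*
the threshold enlarges the altered-gene set and can lower the mean for
drugs far from it. That is the intended behavior of a mean, not a bug.

## Propagation scoring

The 0/1 adjacency $W$ of the extended network is Laplacian-normalized,
$W' = D^{-1/2} W D^{-1/2}$ with $D_{ii} = \sum_j W_{ij}$, and the
driverness vector $Y$ (altered in-network genes carry their scores; all
other genes and all drug nodes carry 0, with **no** driverness threshold —
the 0.05 filter belongs to the distance method, though an optional cutoff
is exposed) is propagated by a random walk with restart:

$$F(t) = (1-\alpha)\,W'F(t-1) + \alpha Y, \qquad F(0)=Y,$$

stopping when $\lVert F(t)-F(t-1)\rVert_2 < 10^{-4}$ or after 1000
iterations. A drug's score is its final propagation score.

Because $W'$ is a symmetric normalized adjacency, its spectral radius is
at most 1, so for $\alpha>0$ the update is a contraction with factor at
most $1-\alpha$: the iterate converges geometrically to the closed form
$F^* = \alpha\,(I-(1-\alpha)W')^{-1}Y$, and the test suite checks the two
routes against each other. The stopping rule bounds the remaining error by
$\tfrac{1-\alpha}{\alpha}\,\mathrm{tol}$ — about $19\times$ the tolerance
at the default $\alpha$ — which is what the tests use as the agreement
band. Hitting the iteration cap yields a flagged result plus a warning
rather than an error: with these defaults convergence typically takes a
few dozen iterations, so non-convergence signals pathological input worth
surfacing, not crashing on.

Parameters, with defaults and rationale:

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | restart probability; small values let signal diffuse far before being pulled back to the prior. `alpha_sweep()` scores a grid of values for sensitivity checks; judging the resulting rankings is left to the analyst. |
| `tol` | 1e-4 | L2 stopping threshold on successive iterates |
| `max_iter` | 1000 | iteration cap; reached only on pathological input |

Design choices that were genuinely open:

* **Symmetric drug edges.** The distance method treats drug–target edges
  as usable only drug-outward; the propagation update has no directionality
  mechanism, and the network is undirected by construction, so $W$ is kept
  fully symmetric — drug nodes both receive and relay mass. An asymmetric
  variant would need a non-symmetric normalization and loses the
  contraction guarantee above.
* **Isolated nodes** have degree 0, making $D^{-1/2}$ undefined; their
  rows and columns of $W'$ are set to zero, so they neither send nor
  receive and isolated drugs score exactly 0 — consistent with the
  distance method's unreachable ⇒ 0 contract.
* **Determinism.** The node ordering (sorted genes, then sorted drug
  nodes, the latter carrying an internal `drug::` prefix that keeps the
  namespaces disjoint) is fixed, so results are bit-reproducible.

## Selection and tier evaluation

`top_n_with_ties()` returns every drug scoring at least as high as the
*n*-th: if ranks 6 and 7 tie with rank 5, a top-5 selection has 7 drugs.
Tie comparison uses exact floating equality — the distance scorer
genuinely produces exact ties (drugs with identical distance/driverness
patterns), and an epsilon would turn near-misses into spurious ties.
Within the list, equal scores are ordered lexicographically by drug name
for determinism.

Tier annotation takes a local table mapping drugs to the 10-level
clinical-support taxonomy (1A approved for the cancer type under study,
1B approved for other cancer types, 2A/2B in trials, 3–4 curated/inferred
associations, 5 repurposed for cancer, 6 no support); drugs missing from
the table default to tier 6. `tier_proportions()` reports the per-tier
shares plus three summaries: *supported* (tiers 1A–5), *approved/trial*
(tiers 1–2) and *indicated-for-type* (1A, 2A, 3A, 4A). Building the tier
table from annotation services is out of scope: those are versioned
external resources, and baking a snapshot in would silently go stale.

## The synthetic fixture generator

`generate_fixture()` emulates the *shape* of the three real inputs so the
full pipeline and its edge cases run with zero downloads:

* a random gene graph — Barabási–Albert with attachment 2 by default,
  since real PINs are heavy-tailed; Erdős–Rényi as the alternative;
* 20 drugs with 1–3 targets each, a configurable fraction of drug pairs
  sharing identical target sets (exercising the merge path) and a
  configurable fraction of target slots pointing at symbols outside the
  network (exercising orphan handling);
* a driverness mixture in which 80% of altered genes fall in [0, 0.05] —
  below the distance filter — and 20% in [0.5, 1], mimicking the sparse
  high-driverness profile real driver-prioritization output shows, and
  making the threshold path do real work in every test.

All randomness flows from the single `seed`; identical spec and seed give
byte-identical TSV output. `planted_signal_fixture()` additionally builds
a shuffled path network in which one drug directly targets the unique
high-driverness gene while all decoy targets sit at least 3 hops from
every altered gene, so both scorers must rank the planted drug first —
a recoverable ground truth no purely random fixture provides.

What the generator does *not* emulate: the degree distribution or size of
any specific PIN release, drug-name vocabularies (salts, brand names) and
their aliasing, or correlated alteration patterns across genes. Passing
tests therefore demonstrate algorithmic correctness on networks with
realistic sparsity and tail behavior, not performance claims about any
particular clinical dataset.

## Problem sizes and numerical tolerances

The test suite cross-checks the distance scorer against a literal
Floyd–Warshall-plus-formula reference on one hundred fixtures of up to 50
genes (agreement to 1e-12; the computation is exact integer hop counting,
so only summation order separates the routes), and the propagation scorer
against dense direct solves on fixtures of up to ~200 nodes. Monotonicity
properties (driverness bumps, edge additions) are exercised on 200
randomized cases per suite at 25 genes each. These sizes make the whole
suite run in well under a minute while still covering disconnected
components, merged drugs, orphan targets and empty driver sets; the
algorithms themselves are sparse and scale to realistically sized PINs.

## Known limitations

* No gene-identifier mapping: symbol mismatches between inputs silently
  become "absent from network" cases (warned about, but not resolved).
* Hop distances ignore edge confidences; a high- and a low-confidence
  edge count the same once past the load filter.
* The propagation scorer's scores depend on drug degree through the
  normalization — a drug with many targets dilutes incoming mass per
  edge; this is a property of the model, not an implementation artifact.
* Cancer type enters only through the upstream driverness scores; there
  is no per-cancer-type logic in the scorers themselves.
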