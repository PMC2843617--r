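---
title: "ListNet: models, parameters and design decisions"
author: "ListNet maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ListNet: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ListNet)
```

ListNet integrates gene and protein lists from high-content experiments:
it normalizes symbols, applies set algebra, tests overlap against
annotated gene-set libraries with the Fisher exact test, expands seed
lists into connecting subnetworks over background interaction networks,
and assembles a "network of lists" from statistically significant
overlaps. This vignette explains the underlying models, the parameters
that matter, the behaviour of the synthetic-data generators, and the
choices we made where more than one defensible design existed.

## Symbols, lists and libraries

Everything operates on gene *symbols* (the human convention: upper-case
tokens), not numeric identifiers. `normalizeSymbol()` trims whitespace
and upper-cases; the transformation is idempotent, so re-normalizing a
stored list is a no-op. An optional two-column synonym table
(alias → canonical) is applied at normalization time. The table must be
flat — an alias maps directly to its canonical symbol, and canonicals
never map onward — which the constructor enforces, so resolution is a
single lookup with no chains or cycles. No synonym database is bundled;
the hook accepts whatever mapping the user trusts. Cross-namespace
conversion (Entrez ID ↔ Ensembl ↔ UniProt) and orthology mapping are
out of scope.

A `GeneList` stores unique symbols in first-occurrence order; a
`GeneSetLibrary` is an ordered collection of uniquely named lists, as
one GMT file. GMT rows commonly contain duplicate symbols in the wild,
so the reader deduplicates silently and exposes per-set drop counts via
`duplicatesDropped()`. The description column is preserved verbatim and
never used in computation. Set operations follow plain set semantics on
the symbol sets; `setUnion(a, b)` keeps a's order and appends b's
novelties, which keeps results reproducible without imposing a sort.

## The overlap model

For a user list and a library set, restricted to a background universe
of $N$ genes where they have $a$ and $b$ members and share $k$, the
one-sided over-representation p-value is the hypergeometric upper tail

$$P = \sum_{i=k}^{\min(a,b)} \frac{\binom{b}{i}\binom{N-b}{a-i}}{\binom{N}{a}},$$

equivalent to the one-sided Fisher exact test on the 2×2 membership
table. We use the one-sided test because enrichment analysis asks
specifically for *unexpectedly large* overlap. The tail sum is
evaluated in log space (`lchoose` with log-sum-exp), which is exact to
floating-point precision and does not overflow for universes of tens of
thousands of genes. The null treats genes as independent draws; genes
are of course co-regulated in reality, so p-values are anti-conservative
to an unknown degree — a standard, explicitly accepted simplification
in this family of methods.

**The universe $N$.** The choice of background changes every p-value,
so it is an explicit policy rather than a hidden constant:

* `"library"` (default): the union of the library's own genes. This is
  self-contained and reproducible; a user gene outside it is dropped
  from $a$ (and reported) rather than added to $N$, because a gene the
  library has never annotated carries no information about any term.
* `"union"`: library universe plus all user-list genes — appropriate
  when user lists are drawn from a wider assay background.
* an explicit symbol vector, when the assay's true background (e.g. all
  genes on the array) is known.

**Corrections.** Bonferroni ($\min(1, np)$) and Benjamini–Hochberg
(step-up) are computed per user-list column over the library's sets,
matching how one inspects one list's enrichment ranking at a time; a
`correction = "matrix"` mode corrects over all cells at once for users
who treat the whole matrix as one family. Ranked tables
(`rankTerms()`) sort by raw p ascending, breaking ties by descending
overlap size and then label, so output order is total and
deterministic.

## Background networks

`BackgroundNetwork` wraps a simple undirected igraph: construction
normalizes symbols, merges duplicate and reversed-duplicate edges, and
drops self-loops (counted, since a self-interaction row in a PPI export
is information the user may want to know was discarded). Three builders
cover the usual sources:

* **PPI / custom**: SIF edge lists (`node relation node`); relation
  strings are kept as edge attributes but ignored by all algorithms,
  and single-field rows are honoured as isolated nodes so that
  write∘read round-trips node sets exactly.
* **Co-expression**: a 3-column weighted pair table thresholded at a
  user cutoff (inclusive). Duplicate pairs keep their maximum weight
  *before* thresholding, so a pair reported at 0.9 and 0.4 survives a
  0.5 cutoff. Correlation scales differ between databases, so the
  cutoff has no default.
* **Co-annotation**: genes connected when they co-appear in a library's
  sets. We score co-appearance with the Jaccard index over set
  membership — shared sets over either-membership sets — which is
  symmetric, bounded in [0, 1], equals 1 exactly for identical non-empty
  membership and 0 for disjoint membership. It is a similarity; the
  corresponding distance is $1 -$ score. The measure lives behind a
  single function (`coannotationScore()`) so an alternative (cosine,
  raw co-occurrence count) can be swapped without touching the graph
  builder. The edge cutoff is inclusive: cutoff 1 keeps
  identical-membership pairs.

The interactor browser (`interactorTree()`) is a breadth-limited BFS:
level 1 lists direct interactors, level $d$ the interactors of level
$d-1$, each annotated with its background degree; a node already shown
is marked as a revisit and not expanded again, which is what makes the
recursive display finite on cyclic graphs.

## List expansion

`expand()` connects the seeds of a list through a background network.
Two parameters control the result:

* `maxSteps` (default 2): the maximum shortest-path length, in links,
  between a seed pair for that pair to be bridged. Step 1 (direct
  seed–seed edges) is always included; pairs farther apart than
  `maxSteps` are simply left unconnected, not an error.
* `specificityCutoff` (default 0, range [0, 1]): the minimum
  *specificity* for an intermediate to be admitted, where specificity
  is the fraction of the node's background links that go to seeds.
  This is the knob that keeps promiscuous hubs — which lie on shortest
  paths between almost everything — out of the subnetwork.

Design choices that were genuinely open:

* **All shortest paths, not one.** For a seed pair at distance $d$ we
  enumerate every length-$d$ path. Taking a single arbitrary path would
  make output depend on adjacency ordering; taking all of them makes
  the result canonical and order-independent.
* **Filter after enumeration, against the original background.**
  Specificity is defined against the full background network, computed
  once per candidate; candidates below the cutoff are removed together
  with every path through them, and surviving paths are not re-grown.
  A consequence: a high-specificity node admitted only via paths that
  also carry a failing node is dropped with those paths. This
  single-pass semantics is deterministic and matches the definition of
  specificity as a background property, not a subnetwork property.
* **Path-union, not induced-subgraph, edges.** The subnetwork's edges
  are exactly the union of admitted path edges plus seed–seed background
  edges; background edges between two admitted intermediates that lie
  on no admitted path are excluded, so every edge in the output is
  there for a stated reason.
* **Missing seeds survive.** Seeds absent from the background are
  excluded from path finding (with a warning) but retained at the end
  of the expanded list — the user's list membership should not be
  silently erased by a network's incompleteness.

Intermediates are ranked by subnetwork-links over background-degree,
ties by descending subnetwork links and then label.
`subnetworkToList()` emits seeds first (input order), then
intermediates in rank order, under the original name with an
`_expanded` suffix. `writeSIF()` writes each unordered edge once, with
endpoints and rows in lexicographic order, plus a node-attribute
sidecar (role, specificity, rank) — the layout Cytoscape imports
directly.

## The network of lists

`buildListsNetwork()` connects a user list to a library set when the
Bonferroni-corrected overlap p-value is strictly below `alpha`
(default 0.05; strict inequality, and Bonferroni rather than BH, is the
deliberately conservative edge rule). Correction is per user-list
column, so adding or removing one user list never changes the
corrected p-values between the others and the library. User–user list
pairs are tested too (flag on by default), corrected over the number of
user pairs as their own family, since no stated family links them to
the library tests. Node classes partition the graph: user lists are
`input` always (even when they overlap each other); library sets are
`single_overlap` with exactly one significant input edge,
`multi_overlap` with two or more; sets with no significant edge are
omitted. The classes correspond to the blue/green/black colouring
convention of list-network visualizations; rendering is left to the
consumer (GraphML attributes, or SIF plus an attribute sidecar, both in
deterministic row order).

## Synthetic data: what it emulates, what it does not

The `fixtureSpec()` generators exist so the statistical machinery is
testable end-to-end without downloading any database. All of them are
pure functions of the spec — a private RNG stream is seeded from
`spec$seed` and the caller's random state is restored — so identical
specs give byte-identical fixture files.

* `makeUniverse()` names genes `G000001…`: structureless by design.
* `makeLibrary()` samples each set uniformly without replacement. With
  `planted`, one randomly designated set shares *exactly*
  `round(overlapFraction × userSize)` genes with a generated user list
  whose remaining genes are drawn outside that set; the construction is
  exact, not in expectation, so recovery tests have a sharp target. The
  default conditions — a 2,000-gene universe, 50 sets of 50–300 genes,
  a 50-gene user list sharing 40 genes with the planted term — give a
  planted signal (raw p around $10^{-27}$) that decoy overlaps
  (hypergeometric noise around 2–8 genes) cannot reach, which is what a
  clearly enriched pathway in a curated library looks like.
* `makeNetwork()` offers `chain` and `star` (exact topologies, used by
  oracle tests), `erdos_renyi`, and `preferential_attachment`
  (Barabási–Albert, `m = 2`), whose heavy-tailed degree distribution
  mimics the hubbiness of real PPI networks.

What the generators do **not** emulate: correlated gene membership
across sets (real pathways overlap each other), annotation bias (well
studied genes appear in more sets), degree-correlated annotation, and
noisy symbol aliases. Passing the planted-recovery test therefore shows
the ranking machinery works under its null model, not that real-library
enrichment p-values are well calibrated — on real data the independence
assumption makes them optimistic.

## Numerical and degeneracy conventions

* Tail sums in log space; p-values capped at 1; $k = 0$ gives exactly 1.
* A list empty after universe restriction yields a degenerate
  `OverlapTest` ($k = 0$, $p = 1$, flagged) rather than an error, so one
  bad column cannot abort a matrix.
* p-value validators require entries in $(0, 1]$; 0 is rejected as it
  cannot arise from the exact test.
* Specificity is undefined for isolated nodes (rejected explicitly).
* Every ordering in the package (matrix rows, ranked tables, SIF rows,
  BFS discovery) has a stated total order, so equal inputs give
  byte-equal outputs.

## Problem sizes in the test suite

The bundled tests run the Fisher implementation against an
exact-integer oracle over several thousand $(N \le 60, a, b, k)$
instances, the corrections against an independently coded step-up
reference on 1,000 random vectors, planted-term recovery over 200
seeded replicates at the default study conditions, and the expansion
algorithm against exhaustive path enumeration on 500 random connected
graphs of up to 12 nodes; round-trip identities (GMT, SIF) are checked
on 100 random objects each. These sizes give the property tests dense
coverage of the small-instance space while keeping the default suite
quick to run.

## Known limitations

* Fisher-exact only; no rank-based (Kolmogorov–Smirnov/Wilcoxon)
  enrichment.
* The gene-independence null is optimistic on real, co-regulated data.
* Expansion is strict shortest-path semantics — no Steiner-tree
  optimization, no probabilistic edge weighting; a background edge
  weight influences co-expression thresholding but never path length.
* Symbols only; no identifier or species mapping.
* No bundled PPI/co-expression/annotation databases; the package
  consumes whatever SIF/TSV/GMT the user provides, and its synthetic
  generators for testing.
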