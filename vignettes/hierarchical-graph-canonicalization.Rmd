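---
title: "Canonical labeling of hierarchical molecule graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Canonical labeling of hierarchical molecule graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hnauty)
```

## The modeling problem

Rule-based models of cell signaling represent molecules as graphs: a colored
vertex is a molecular component (a protein, a domain, a linear motif, a
residue), a vertex attribute is a component's internal state (say, a
tyrosine's phosphorylation status), and an edge is a bond.  Flat graphs of
this kind cannot say that Y192 *sits inside* the SH2 domain of Lck.  This
package therefore works with graphs carrying **two edge types**: directed
*hierarchy* edges (type 0) expressing containment, and undirected *bond*
edges (type 1) expressing molecular bonds.  A *molecular entity graph* lists
each component's possible internal states; a *chemical species graph* is the
same graph with every variable state assigned a concrete value.  Labels
never change; attributes may.

Containment is normally a tree (a *strict hierarchy*), but overlapping
linear motifs break tree-ness: in the CD3&epsilon; chain of the T-cell
receptor complex, tyrosine Y188 belongs to both the proline-rich sequence
and the ITAM, so it has two parents.  Any directed *acyclic* containment
relation is accepted as a *pseudo-hierarchy*; a directed cycle is invalid.
A component declared as its own parent is a root, represented internally by
the absence of an outgoing hierarchy edge, which keeps the adjacency
encoding loop-free and the acyclicity check simple.

```{r}
classify_hierarchy(lck_species())
classify_hierarchy(tcr_complex())
```

## The adjacency encoding

A graph with `m` edge types is stored in one integer matrix: entry
\((i, j)\) is \(\sum 2^e\) over the edge types \(e\) present between \(i\)
and \(j\).  An undirected-type edge contributes to both symmetric entries, a
directed-type edge only to the source-to-target entry.  With the molecular
convention the entries are 0, 1 (hierarchy), 2 (bond) or 3 (both):

```{r}
encode_adjacency(lck_species())
```

The encoding is exactly invertible for graphs without two same-type edges
between one pair (`decode_adjacency()`), a restriction that is natural for
molecular graphs and enforced at construction.  The row-major integer
serialization of this matrix, prefixed by the initial color-class
structure, is the unit of comparison for canonical labels.

An alternative route to a single-edge-type representation is
`flatten()`, which replaces each typed edge by an inserted marker vertex
("h" or "b") joined to both endpoints.  The transform is defined so that no
information is lost: for a *directed* edge \(x \to y\) the inserted vertex
\(v\) receives the arcs \(x \to v\) and \(v \to y\), while an undirected
bond's marker receives both arcs inward.  A plain undirected insertion
would erase hierarchy-edge direction; inheriting the edge's directedness is
the package's choice that makes flattening preserve *and* reflect
isomorphism, which the tests check against a brute-force oracle.

## Equitable refinement

An ordered partition of the vertices is *generalized equitable* when, for
every edge type (and, for directed types, each arc direction separately),
any two vertices in a cell have equal edge counts into every cell.
Splitting on direction is stricter than required by the undirected
definition, remains isomorphism-invariant, and lets the refinement separate
parents from children.  Every partition has a unique coarsest generalized
equitable refinement; `coarsest_equitable_refinement()` computes it by
splitting every cell on its full count vector, simultaneously, until
nothing splits.  Any splitting schedule reaches the same cells; the
simultaneous full-pass schedule is chosen for determinism and speed (each
pass is a handful of matrix products).

Cell *order* is the delicate part, because the search-tree leaves inherit
it.  Fragments of a split cell replace the cell in place and are ordered by
a two-part key: first their count vectors **sorted in decreasing order**
(compared descending, so cells of higher degree come before cells of lower
degree), then -- only to break ties in that multiset -- the raw count
vector, ascending lexicographically.  This is the one convention we found
that simultaneously reproduces the classical worked examples for the two
five-vertex demonstration graphs: both their coarsest equitable partitions,

```{r}
coarsest_equitable_refinement(fixture_g1())
coarsest_equitable_refinement(fixture_g2())
```

and the two search leaves worked out below.  A plain descending
lexicographic comparison on the raw vector reproduces the partitions but
swaps the leaves' final cells; plain ascending reproduces the leaves but
reverses the partitions.  The tie-break matters only when two fragments
have the same count multiset, which is exactly where the printed examples
disambiguate the convention.

## The search: individualization and refinement

The canonical labeler is a depth-first search in the style of Nauty,
generalized to typed edges.  The initial partition groups vertices by color
key -- label, possible-attribute list, and assigned attribute, so a
phosphorylated and an unphosphorylated tyrosine are different colors --
with cells in byte-lexicographic key order, making the whole computation
independent of input vertex order.  The root is the coarsest equitable
refinement of that partition.  At each non-discrete node the first cell
with more than one vertex is the target; each of its vertices in turn is
*individualized* (moved into its own cell, placed before the remainder) and
the partition re-refined.  Leaves are discrete partitions, i.e. vertex
orderings:

```{r}
enumerate_leaves(fixture_g2(), pruning = "none")
```

Two prunings cut the tree without changing the result.  *Automorphism
pruning*: when two leaves yield equal permuted matrices, composing one
ordering with the other's inverse gives an automorphism; later siblings
lying in the orbit of an explored sibling under the discovered generators
(restricted to those fixing the individualized vertices) are skipped.
*Indicator pruning*: each node carries the sequence of partition shapes
along its root path -- a permutation-invariant quantity -- and branches
whose shape sequence compares greater than the current best leaf's (and do
not lie on the first leaf's track, which is kept for automorphism
discovery) are skipped.

The canonical form is the leaf minimizing the pair (indicator path,
serialized matrix), under lexicographic comparison of the row-major integer
sequence -- the natural generalization of comparing binary strings once
entries can exceed 1.  Using the same two-stage rule in *every* pruning
mode is what makes the three modes provably agree: automorphism pruning
only removes leaves with a surviving twin of identical path and string, and
indicator pruning only removes leaves that lose the first comparison.

One caveat is worth stating plainly.  The minimum over *search leaves* is
not, in general, the minimum over *all* vertex orderings.  For the
five-cycle-plus-chord graph above, the globally smallest row-major string
starts at the degree-2 vertex v2, but the worked leaf set -- which the
degree-descending convention pins down -- contains only orderings starting
at v1 or v3.  Since the leaf set is closed under automorphisms and the
selection rule is permutation-invariant, the label is still a true
canonical form: equal exactly for isomorphic graphs.  The test suite keeps
one literal exhaustive-minimum comparison to document the divergence, and
verifies the properties that actually matter -- permutation invariance and
exact agreement of label *equality* with brute-force isomorphism -- over an
exhaustive suite of all single-type graphs on up to 5 vertices and hundreds
of seeded two-type graphs.

`automorphism_count()` closes the discovered generators under composition;
for the demonstration graphs it gives 2 for the chordal cycle and 12 for
the complete bipartite graph \(K_{2,3}\) (which equals
\(2! \cdot 3!\), the product of the two side symmetries, confirmed by
enumerating all 120 permutations).

## The randomized self-test

`sample_graph()` draws Erdős–Rényi graphs with two edge types: per
unordered pair, an undirected bond edge with probability 0.1, a directed
hierarchy edge with probability 0.05 (orientation uniform -- the symmetric
default, since nothing pins it down), otherwise no edge.  These defaults
are the study conditions for the permutation self-test:
`run_self_test(1000, n = 200)` samples one thousand 200-vertex graphs,
applies an independent uniform vertex permutation to each, and demands
label equality in every single trial.  The full run takes a few minutes
(one 200-vertex labeling is ~0.2 s, dominated by two or three refinement
passes of dense matrix products); the unit tests use a 50-graph, 20-vertex
smoke version of the same property, and the full 1000-graph run lives in
the acceptance tests.

What the generator emulates -- and what it does not: independent-pair
random graphs at these densities are almost surely rigid, so the
permutation test mostly exercises the refinement and encoding machinery,
not deep search-tree pruning.  Symmetric regimes are covered instead by the
exhaustive small-graph suites (edgeless and complete graphs generate all
\(n!\) leaves) and by the fixtures (the expanded TCR complex has an exact
two-fold dimer symmetry).  Real chemical species graphs are sparser, more
modular and more heavily colored than these random graphs; colors only make
canonicalization easier, so the one-color random suite is the harder
regime.

## Numerical and degenerate-input choices

* Vertex ids are opaque strings; two vertices may share a label.  Self
  edges are rejected (self-parent input in files is the only exception
  conceptually, and it is represented by edge absence).
* Same-type parallel edges are rejected rather than encoded, matching the
  invertibility condition of the power-of-two encoding.
* Ties between split fragments cannot occur (fragments are key-distinct by
  construction); the documented two-part comparator is total.
* Shape vectors are 1-based and truncated at the largest occurring cell
  size; shape sequences of unequal length compare shorter-prefix-first.
* The empty edge set, single-vertex graphs and attribute-free graphs are
  all legal and covered by tests; the trivial partition of a regular graph
  is its own coarsest equitable refinement.
* All iteration orders are fixed by partition order or byte-lexicographic
  sorting; nothing in the labeler consumes randomness.

## Problem sizes used by the test suite

Exhaustive: all \(2^{\binom{n}{2}}\) single-type graphs for
\(n \le 5\) (1099 graphs), with brute-force oracles capped at 8 vertices.
Seeded: 500 two-type graphs on 7 vertices for oracle comparisons, plus the
1000-graph, 200-vertex self-test above.  These sizes were chosen so the
brute-force oracles stay exact while still covering every small-graph
symmetry class.

## Known limitations

* No guarantee of polynomial behavior on adversarial highly symmetric
  inputs; the search falls back to near-exhaustive enumeration there, as
  all individualization-refinement labelers do.
* The label is canonical for the convention set documented here; labels
  are not interchangeable with those of other labelers (including the
  exhaustive minimum-string label, as discussed above).
* Graph rewriting, rule application and reaction-network generation are
  out of scope: this package supplies the graph model, the encoding and
  the labeler.
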