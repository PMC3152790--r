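# hnauty

Canonical labeling and isomorphism testing for graphs with multiple edge
types, as used in rule-based modeling of multi-component biomolecules.

## The problem

In rule-based models of cell signaling (BioNetGen-style), a molecule is a
graph: colored vertices are components (protein, domain, linear motif,
residue), vertex attributes are internal states (a tyrosine is `U` or `P`),
and edges are bonds. Plain bond graphs cannot express that Y192 *sits
inside* the SH2 domain of Lck, so this package models molecules as
**hierarchical graphs** with two edge types: directed *hierarchy* edges
(type 0, "contains") and undirected *bond* edges (type 1). Containment may
be a tree (strict hierarchy) or any DAG (pseudo-hierarchy — e.g. tyrosine
Y188 of CD3ε belongs to both the PRS and the ITAM).

During network generation such a tool must decide, over and over, whether a
newly produced chemical species graph already exists — a graph-isomorphism
question best answered by *canonical labels*: strings equal exactly for
isomorphic graphs. The package implements **HNauty**, an
individualization-and-refinement canonical labeler in the style of Nauty,
generalized to any number of edge types:

* a graph with `m` edge types is encoded in one integer matrix with entry
  `(i,j) = Σ 2^e` over the edge types `e` between `i` and `j` (undirected
  edges fill both symmetric entries, directed edges only one — so the
  two-type entries are 0, 1, 2, 3);
* partitions of the vertex set are refined to the unique coarsest
  *generalized equitable* partition — for every edge type and arc
  direction, vertices sharing a cell have equal edge counts into every
  cell (the per-type version of `d(x, S_j) = d(y, S_j)`);
* a depth-first search individualizes vertices of the first non-singleton
  cell, re-refines, and selects among the resulting discrete partitions the
  one minimizing (shape-sequence indicator, row-major matrix string);
  automorphisms discovered from equal-matrix leaves prune symmetric
  subtrees.

Brute-force oracles (`brute_canonical()`, `brute_automorphisms()`), a
seeded two-edge-type Erdős–Rényi generator with a permutation self-test,
a line-oriented graph file format, and worked fixtures (Lck, the TCR
complex, the classical five-vertex demonstration pair) round out the
package.

## Worked example

```r
library(hnauty)

# the chemical species graph of Lck: SH2 bound to phosphorylated Y505
encode_adjacency(lck_species())
#>      Lck SH3 SH2 Y505 PTK Y192 Y394
#> Lck    0   1   1    1   1    0    0
#> SH3    0   0   0    0   0    0    0
#> SH2    0   0   0    2   0    1    0
#> Y505   0   0   2    0   0    0    0
#> PTK    0   0   0    0   0    0    1
#> Y192   0   0   0    0   0    0    0
#> Y394   0   0   0    0   0    0    0
```

Each `1` is a hierarchy edge (row contains column: Lck contains SH3, SH2,
Y505 and PTK; SH2 contains Y192; PTK contains Y394), and the symmetric pair
of `2`s is the intramolecular SH2–Y505 bond.

```r
# the five-cycle v1..v5 with chord v1-v3: coarsest equitable partition
coarsest_equitable_refinement(fixture_g2())
#> ({v1,v3}, {v2}, {v4,v5})

# its automorphism group has order 2 (the v1<->v3, v4<->v5 reflection);
# the complete bipartite K_{2,3} has order 12 = 2! * 3!
automorphism_count(fixture_g2())   # 2
automorphism_count(fixture_g1())   # 12

hnauty_canonical(lck_species())
#> <canonical_form>
#>   permutation: Lck PTK SH2 SH3 Y192 Y394 Y505
#>   label: Lck~~x1;PTK~~x1;SH2~~x1;SH3~~x1;Y192~P,U~Ux1;Y394~P,U~Ux1;Y5 ...
#>   search: 1 nodes, 1 leaves, 0 generator(s)
```

The label couples the color-class structure (label, possible states,
assigned state, class size) with the canonically permuted matrix; two typed
graphs are isomorphic exactly when their labels match
(`are_isomorphic()`).

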