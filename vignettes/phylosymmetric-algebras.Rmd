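---
title: "Phylosymmetric algebras: models, methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylosymmetric algebras: models, methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylosym)
```

## The model

Continuous-time Markov models of sequence evolution are specified by a rate
matrix $Q$: off-diagonal entries are rates of change between states, rows
sum to zero.  This package builds *parameterised* rate-matrix families from
a rooted tree $\mathcal{T}$ whose leaves are the states (taxa) and whose
non-leaf vertices each carry a free rate parameter.  The rate of change
between two states $x, y$ is defined to be the rate at their most recent
common ancestor, $\omega(\mathrm{mrca}(x, y))$.

Fixing a rate $\alpha$ at vertex $u$, collecting all ordered pairs with
$\mathrm{mrca}(x,y) = u$ gives a class $C_\alpha$; the classes over all
non-leaf vertices, together with the diagonal pairs, partition $X \times X$.
Each class yields a symmetric integer basis matrix
$$
(Q_\alpha)_{xy} = \begin{cases}
1 & \mathrm{mrca}(x,y) = u,\\ 0 & \text{otherwise},
\end{cases}
\qquad
(Q_\alpha)_{xx} = -\#\{z : (x,z)\in C_\alpha\},
$$
and the model is the real span of these matrices: every element has the
block pattern shown by `export_symbolic()`, with the diagonal determined by
zero row sums.  When every rate is distinct the span is closed under matrix
multiplication — a commutative matrix algebra, here called a
*phylosymmetric algebra*.  Closure matters in practice: for a matrix
algebra, the transition-matrix family is simply
$\{I + Q : \det(I + Q) \neq 0\}$, so one can work without matrix
exponentials.

## Graph view

Each rate also defines an *mrca graph* $G_\alpha$ on the taxa, with an edge
$(x,y)$ iff $\mathrm{mrca}(x,y)$ carries the rate.  Its non-isolated part
is complete $k$-partite, the parts being the leaf sets of the children of
$u$, and the basis matrix is the negative graph Laplacian:
$Q_\alpha = -L(G_\alpha) = A - D$.  The collection of mrca graphs over all
rates is a *tree-induced graph set* (TIGS): pairwise edge-disjoint graphs
covering the complete graph, each a complete multipartite component plus
isolated vertices, with every multi-element part being the support of
exactly one other graph.  TIGS on $X$ are in bijection with hierarchies
(laminar families) on $X$, hence with rooted trees; `hierarchy_to_tigs()`
and `tigs_to_hierarchy()` implement the two directions and
`validate_tigs()` certifies arbitrary hand-built graph sets condition by
condition, without reference to any tree.

## Multiplication structure

Products of basis matrices have closed forms determined by the relative
position of the two vertices ($|T^\alpha|$ denotes the number of leaves
below $u$, and $|T^\alpha_\beta|$ the number of leaves below the child of
$u$ on the path to $v$):

* incomparable vertices: $Q_\alpha Q_\beta = 0$;
* $v$ a strict descendant of $u$:
  $Q_\alpha Q_\beta = (|T^\alpha_\beta| - |T^\alpha|)\, Q_\beta$;
* squares, entrywise on the support of $G_\alpha$ with degrees $d_i$:
  diagonal $d_i(d_i+1)$, entries $-|T^\alpha|$ across parts and $d_i$
  within a part.

The square's *expansion in the basis* is not taken from any printed
closed-form formula: the entrywise form above is authoritative, and
`product_coeffs()` recovers the expansion by exact coefficient extraction
(`span_coeffs()`).  The reason is a numerical check we consider decisive:
on the five-taxon worked example the square of the three-leaf subtree rate
expands as $-3\,Q_\gamma + Q_\delta$, which disagrees with the most natural
reading of the usual printed expansion ($-2\,Q_\gamma + Q_\delta$).  The
extraction route is immune to that ambiguity, and every expansion the
package emits is validated against the brute-force integer matrix product.
The equivalent derived closed form, validated by the same oracle, is
$Q_\alpha^2 = -|T^\alpha| Q_\alpha + \sum_{v \in \mathrm{ch}(u)}
(|T^\alpha| - |T^{\omega(v)}|)\, J_v$ with $J_v$ the subtree sum matrix
below.

Span membership is decidable exactly because basis supports are disjoint
and carry entries 1: the only candidate coefficient for each basis element
can be read off any one of its support cells, and membership holds iff the
implied combination reproduces the matrix entry-for-entry.  All of this is
integer arithmetic; the package uses no floating-point tolerance anywhere
in the decision path.

### The subtree sum matrix

Summing the basis over all vertices of the subtree rooted at $u$ (with $m$
leaf descendants) gives $J_u$: 1 at off-diagonal pairs of descendants and
$-(m-1)$ on their diagonal.  We implement the diagonal as $-(m-1)$, not
$-m$: the subtree on $m$ leaves behaves as a full tree on $m$ taxa, whose
basis sums to the $m \times m$ matrix with diagonal $1 - m$.  The
alternative diagonal $-m$ is inconsistent with the sum identity on the
five-taxon example (the three-leaf subtree sums to diagonal $-2$), which
the test suite checks exactly; we treat the $-m$ variant as a typo in the
source tradition and record the choice here.

## Constrained models and the closure decision

Setting two rates equal replaces the two basis matrices by their sum
(`merge_basis()`).  The merged span is always *contained* in the
unique-rate algebra but need not be closed itself.  For a single merged
pair the outcome is completely characterised by five mutually exclusive
configurations of the two vertices (`classify_pair()`): closure holds iff
they are parent and child, or siblings with equally many leaf descendants.
The package treats this characterisation as a theorem to be *verified at
run time*: `decide_algebra()` always runs the generic exact closure check
and cross-validates any theorem-based shortcut against it, erroring loudly
on disagreement rather than trusting either side.

For arbitrary rate partitions the general characterisation is open; the
decision procedure is the generic closure check, with two sufficient
conditions reported when they apply:

* *connected identification*: every non-singleton class induces a connected
  (parent–child) subgraph of the tree — contracting those edges one at a
  time yields a smaller tree's algebra;
* *one equal-size sibling class*: a single class of pairwise siblings with
  a common leaf count.  We deliberately do **not** extend this to several
  sibling classes: two merged classes can interact through cross products
  with unequal coefficients, so only the single-class form is safe as a
  shortcut.

The Kimura two-parameter (K2P) DNA model is the canonical constrained
instance: the tree `((A,G)b,(C,T)c)a;` with $b = c$ merged.  The figure in
the source tradition is not machine-readable as to whether the two cherry
vertices carry one symbol or two symbols later constrained equal; the
package builds the fixture with two labels plus the explicit constraint
`{b, c}`, which is immaterial to the resulting algebra.  The result is a
closed two-dimensional algebra whose generic element has one parameter on
the transitions A↔G, C↔T and a second on all transversions, and
`parameter_count()` returns 2.

## Numeric instantiation

`instantiate()` substitutes real values for the free parameters and
`transition_matrix()` forms $I + Q$ with a determinant-based invertibility
verdict (threshold $10^{-12}$ on the determinant; for the integer and
small-rational values typical here the determinant is computed exactly up
to double precision).  No constraint forces instantiated off-diagonal
rates to be non-negative — the algebraic theory does not need it — but a
`proper` flag reports whether $Q$ qualifies as a genuine rate matrix for
modelling use.

## The random-tree generator

`random_tree(leaf_count, seed, max_children)` emulates the input space the
theory quantifies over: arbitrary rooted trees without degree-2 vertices,
binary by default, polytomous on request.  Topologies come from random
sequential leaf attachment (each new leaf subdivides a uniformly chosen
edge), which at `max_children = 2` samples full binary shapes; polytomies
are then created by contracting each internal edge independently with
probability 0.25 (default) subject to the `max_children` cap.  Defaults
were chosen once: leaf ranges 3–12 for algebra-level checks (the regime
where every structural case — nested, sibling, incomparable — occurs many
times) and 3–7 for the exhaustive pair sweep.  The generator states a
reproducibility contract — same configuration and seed, same tree — and
restores the caller's RNG state.

What a green suite establishes: the algebraic identities hold exactly on
the worked examples and on hundreds of sampled topologies, and the
five-case characterisation agrees with the generic decision on every
sampled pair.  What it does not establish: anything about fit to real
sequence data, about amino-acid model choice, or a proof of the theorems —
the suite is exhaustive machine checking at small scale, not verification.

## Degenerate inputs and tie-breaks

* Trees must have every non-leaf vertex (root included) with at least two
  children; single-child vertices are rejected at parse time.
* `mrca(x, x)` is the leaf itself; leaf vertices carry no rate and
  contribute no basis matrix (their would-be matrix is zero).
* Matrix row/column order is the leaf order of first appearance in the
  Newick text, so worked-example matrices come out in their printed
  orientation; `sort_taxa` forces lexicographic order.
* Branch lengths are parsed and ignored with a warning — rates live on
  vertices.
* Duplicate internal labels are an error unless explicitly requested as a
  merge (`dup_rates = "merge"`), in which case they become an equality
  class handled by the constraint machinery.
* The TIGS validator treats the graph collection as unordered except for
  the unique no-isolated-vertex graph, sidestepping the inconsistent
  indexing conventions sometimes attached to the definition.

## Known limitations

* No complete characterisation for arbitrarily many merged classes is
  attempted (open problem); beyond the shortcuts above the answer is the
  generic closure check, which is exact but names no theorem.
* No likelihood computation, model fitting, or unrooted-tree support.
* The closure decision treats closure for unique rates as holding for all
  trees, binary or not, and verifies it by the exact oracle on every input
  rather than restricting to binary trees.
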