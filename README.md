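# phylosym

Rate-matrix algebras for phylogenetic substitution models, built from
rooted trees.

## The problem

Parameterised substitution models assign free rate parameters to classes of
state changes.  A model whose rate-matrix set is closed under matrix
multiplication (a *matrix algebra*) is computationally attractive: its
transition matrices are just `I + Q` with `det(I + Q) != 0`, no matrix
exponentials required.  `phylosym` constructs such models from a rooted
tree whose **leaves are the states** and whose **non-leaf vertices carry
the free rates**: the rate of change between states `x` and `y` is the rate
at `mrca(x, y)`.

For each rate α at vertex `u` this yields a symmetric integer basis matrix

    (Q_α)_xy = 1  if mrca(x, y) = u,  0 otherwise   (x ≠ y)
    (Q_α)_xx = −(number of y with mrca(x, y) = u)

and the model is the span of these matrices.  With distinct rates the span
is always a commutative matrix algebra (a *phylosymmetric algebra*).
Equivalently, each `Q_α = −L(G_α)`, the negative Laplacian of the rate's
*mrca graph*, and the set of mrca graphs is a *tree-induced graph set*
(TIGS), in bijection with hierarchies on the state set.  Setting rates
equal merges basis matrices; whether the constrained set is still an
algebra is decided exactly — for one merged pair it holds iff the two
vertices are parent/child or equal-size siblings.  The Kimura
two-parameter DNA model is the instance `((A,G)b,(C,T)c)a;` with `b = c`.

The intended use is designing small, interpretable parameterised models
(e.g. for amino acids, with splits encoding biochemical properties: a
binary tree on 20 states gives at most 19 free parameters, fewer under
constraints).

## Worked example

The five-taxon tree `((1,2)beta,(3,(4,5)delta)gamma)alpha;`:

```r
library(phylosym)
tr <- fixture_tree("fig1")
b  <- basis(tr)
b$alpha
#>    1  2  3  4  5
#> 1 -3  0  1  1  1
#> 2  0 -3  1  1  1
#> 3  1  1 -2  0  0
#> 4  1  1  0 -2  0
#> 5  1  1  0  0 -2
```

Rows and columns follow the leaf order of the Newick string; entry (1,3)
is 1 because `mrca(1, 3)` is the root (rate α), and the diagonal −3 makes
row sums zero.  Products collapse to closed forms — α is the root and γ an
internal vertex on 3 of the 5 leaves, so `Q_α Q_γ = (3 − 5) Q_γ`:

```r
product_coeffs(tr, "alpha", "gamma")
#> gamma
#>    -2
```

Merging rates asks whether the constrained model is still an algebra.
β and γ are siblings with 2 vs 3 leaf descendants, so it is not:

```r
decide_algebra(tr, rate_classes(tr, list(c("beta", "gamma"))))
#> NOT closed: product alpha * alpha leaves the span
#> Rationale: single merged pair, case 3 (siblings with unequal leaf counts)
```

The K2P model, as a tree with its cherry rates identified — one symbol on
transitions (A↔G, C↔T), another on transversions, 2 free parameters:

```r
kt <- fixture_tree("k2p")
cat(format_symbolic(export_symbolic(kt, attr(kt, "rate_classes"))), sep = "\n")
#>       A   G   C   T
#>   A   * b=c   a   a
#>   G b=c   *   a   a
#>   C   a   a   * b=c
#>   T   a   a b=c   *
```

## Command line

An installed wrapper lives at `exec/phylosym` inside the package library;
the same interface is callable as `phylosym_cli()`:

```sh
phylosym basis --tree fig1 --out out/            # TSV matrices
phylosym tigs --tree fig1 --out graphs/          # edge lists + manifest
phylosym closure --tree fig1 --merge beta=gamma  # JSON verdict
phylosym check-pair --tree fig1 --pair beta,gamma
phylosym random-tree --leaves 8 --seed 7 --max-children 3
phylosym export --tree k2p                       # symbolic pattern
```

`--tree` accepts a fixture name (`fig1`, `k2p`), a file, or a literal
Newick string; internal node labels are the rate names.

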