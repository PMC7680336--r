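## Shared fixtures and independent oracles for the test suite.

fig1 <- function() fixture_tree("fig1")
k2p <- function() fixture_tree("k2p")

## The four basis matrices of the fig1 tree, frozen from the worked example
## (canonical taxon order 1..5).
fig1_Q <- local({
  tx <- as.character(1:5)
  m <- function(v) matrix(v, 5, 5, byrow = TRUE, dimnames = list(tx, tx))
  list(
    alpha = m(c(-3, 0, 1, 1, 1,
                0, -3, 1, 1, 1,
                1, 1, -2, 0, 0,
                1, 1, 0, -2, 0,
                1, 1, 0, 0, -2)),
    beta = m(c(-1, 1, 0, 0, 0,
               1, -1, 0, 0, 0,
               0, 0, 0, 0, 0,
               0, 0, 0, 0, 0,
               0, 0, 0, 0, 0)),
    gamma = m(c(0, 0, 0, 0, 0,
                0, 0, 0, 0, 0,
                0, 0, -2, 1, 1,
                0, 0, 1, -1, 0,
                0, 0, 1, 0, -1)),
    delta = m(c(0, 0, 0, 0, 0,
                0, 0, 0, 0, 0,
                0, 0, 0, 0, 0,
                0, 0, 0, -1, 1,
                0, 0, 0, 1, -1))
  )
})

## a reproducible batch of random trees covering binary and polytomous shapes
random_tree_batch <- function(n_trees, leaves_min, leaves_max, seed0) {
  lapply(seq_len(n_trees), function(i) {
    nl <- leaves_min + (i - 1L) %% (leaves_max - leaves_min + 1L)
    mc <- if (i %% 3L == 0L) 4L else 2L
    random_tree(nl, seed = seed0 + i, max_children = mc)
  })
}

## Independent oracle: number of length-2 walks from i to j where the first
## edge comes from graph g1 and the second from g2, by explicit enumeration.
count_two_walks <- function(g1, g2, i, j) {
  a1 <- adjacency(g1); a2 <- adjacency(g2)
  sum(vapply(g1$vertices, function(k) a1[i, k] * a2[k, j], numeric(1)))
}

## Oracle for span membership: solve the least-squares system over the
## vectorised basis and check the residual is exactly zero.  Independent of
## the support-extraction route used by span_coeffs().
span_solve_oracle <- function(m, basis) {
  a <- vapply(basis, as.numeric, numeric(length(m)))
  fit <- qr.solve(crossprod(a), crossprod(a, as.numeric(m)))
  resid <- as.numeric(m) - as.numeric(a %*% fit)
  list(in_span = max(abs(resid)) < 1e-9, coeffs = drop(fit))
}
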