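#' @title MRCA partition classes and basis rate matrices
#' @description
#' For a tree with rate labels on non-leaf vertices, the ordered taxon pairs
#' (x, y), x != y, are partitioned by the rate at mrca(x, y).  The class of
#' rate a yields a symmetric integer matrix Q_a with off-diagonal entry 1 at
#' every pair in the class and diagonal chosen for zero row sums.  The set
#' of these matrices over all non-leaf vertices is the basis of the tree's
#' phylosymmetric algebra.  All arithmetic in this module is exact integer
#' arithmetic.
#' @name mrca-basis
NULL

#' MRCA partition classes of a tree
#'
#' @param tree a `phylosym_tree`
#' @return a named list, one entry per non-leaf rate, each a two-column
#'   character matrix of ordered taxon pairs (x, y) with
#'   `rate(mrca(x, y)) == rate`.  Together with the diagonal pairs these
#'   classes partition X x X.
#' @export
mrca_classes <- function(tree) {
  stop_if_not_tree(tree)
  tx <- taxa(tree)
  out <- lapply(rates(tree), function(r) {
    matrix(character(0), ncol = 2,
           dimnames = list(NULL, c("x", "y")))
  })
  names(out) <- rates(tree)
  for (x in tx) {
    for (y in tx) {
      if (x == y) next
      r <- tree$rate[mrca(tree, x, y)]
      out[[r]] <- rbind(out[[r]], c(x, y))
    }
  }
  out
}

## n x n zero integer matrix with taxon dimnames
zero_matrix <- function(tx) {
  matrix(0L, length(tx), length(tx), dimnames = list(tx, tx))
}

#' Basis rate matrix for one rate
#'
#' Off-diagonal entry (x, y) is 1 iff mrca(x, y) is the vertex carrying
#' `rate`; the diagonal is minus the off-diagonal row count, so every row
#' and column sums to zero.  Equivalently (x, y) = 1 iff x and y descend
#' from distinct children of the rate's vertex.
#' @param tree a `phylosym_tree`
#' @param rate a non-leaf rate label
#' @return an integer matrix with taxon dimnames in canonical order
#' @export
basis_matrix <- function(tree, rate) {
  stop_if_not_tree(tree)
  u <- rate_vertex(tree, rate)
  tx <- taxa(tree)
  m <- zero_matrix(tx)
  parts <- lapply(tree$children[[u]], function(w) cluster_of(tree, w))
  k <- length(parts)
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i != j) m[parts[[i]], parts[[j]]] <- 1L
    }
  }
  diag(m) <- -as.integer(rowSums(m))
  m
}

#' Full basis of a tree's phylosymmetric algebra
#'
#' One matrix per non-leaf vertex, keyed by rate label, in preorder.  The
#' off-diagonal supports are pairwise disjoint and jointly cover every
#' off-diagonal cell, so the matrices are linearly independent.
#' @param tree a `phylosym_tree`
#' @return named list of integer matrices
#' @export
basis <- function(tree) {
  stop_if_not_tree(tree)
  rs <- rates(tree)
  out <- lapply(rs, function(r) basis_matrix(tree, r))
  names(out) <- rs
  out
}

#' The all-pairs sum matrix J
#'
#' `j_matrix(n)` has 1 in every off-diagonal entry and 1 - n on the
#' diagonal; it equals the sum of the full basis of any tree on n taxa.
#' @param n number of taxa (>= 2)
#' @param tx optional taxon names for dimnames
#' @return an integer matrix
#' @export
j_matrix <- function(n, tx = NULL) {
  if (n < 2) stop("n must be at least 2", call. = FALSE)
  if (is.null(tx)) tx <- as.character(seq_len(n))
  m <- matrix(1L, n, n, dimnames = list(tx, tx))
  diag(m) <- 1L - as.integer(n)
  m
}

#' Subtree sum matrix J_u
#'
#' The sum of the basis matrices over all vertices in the subtree rooted at
#' `u`: 1 at off-diagonal (i, j) with both taxa descending from `u`,
#' -(m - 1) at the diagonal of each of the m leaf descendants, 0 elsewhere.
#' (The diagonal is -(m - 1), not -m: the subtree on m leaves behaves as a
#' full tree on m taxa embedded in the larger state space.)
#' @param tree a `phylosym_tree`
#' @param u a non-leaf vertex id
#' @return an integer matrix on the full taxon set
#' @export
j_subtree <- function(tree, u) {
  stop_if_not_tree(tree)
  if (is_leaf(tree, u)) stop("u must be a non-leaf vertex", call. = FALSE)
  tx <- taxa(tree)
  below <- cluster_of(tree, u)
  m <- zero_matrix(tx)
  m[below, below] <- 1L
  diag(m) <- 0L
  m[cbind(below, below)] <- -(length(below) - 1L)
  m
}
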