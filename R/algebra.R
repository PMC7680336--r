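#' @title Products, structure constants and closure of the span
#' @description
#' The basis matrices of a tree with unique rates span a commutative matrix
#' algebra.  Products have closed forms governed by the relation between the
#' two vertices: incomparable vertices give the zero matrix; if v (rate b)
#' descends from u (rate a), then Q_a Q_b = (|T^a_b| - |T^a|) Q_b where
#' |T^a| is the leaf count below u and |T^a_b| the leaf count below the
#' child of u toward v; squares follow an entrywise rule on the mrca graph.
#' Everything here is exact integer arithmetic on matrices with disjoint
#' off-diagonal supports, which makes span membership decidable by reading
#' coefficients off support cells.
#' @name algebra
NULL

#' Entrywise closed form of the square of a basis matrix
#'
#' On the support of the rate's mrca graph: diagonal d_i(d_i + 1) where d_i
#' is the vertex degree; -m for taxa in different parts (m the leaf count of
#' the subtree); d_i for distinct taxa in the same part.  Zero elsewhere.
#' Always equal to the brute-force matrix square of [basis_matrix()].
#' @param tree a `phylosym_tree`
#' @param rate a non-leaf rate label
#' @return an integer matrix
#' @export
square_entrywise <- function(tree, rate) {
  stop_if_not_tree(tree)
  u <- rate_vertex(tree, rate)
  tx <- taxa(tree)
  parts <- lapply(tree$children[[u]], function(w) cluster_of(tree, w))
  m_leaves <- leaf_count(tree, u)
  d <- stats::setNames(rep(0L, length(tx)), tx)
  for (p in parts) d[p] <- m_leaves - length(p)
  out <- zero_matrix(tx)
  for (i in seq_along(parts)) {
    for (j in seq_along(parts)) {
      pi <- parts[[i]]; pj <- parts[[j]]
      if (i == j) {
        out[pi, pi] <- d[pi][1L]         # same part, off-diagonal
      } else {
        out[pi, pj] <- -m_leaves         # different parts
      }
    }
  }
  supp <- unlist(parts)
  out[cbind(supp, supp)] <- d[supp] * (d[supp] + 1L)
  out
}

## empty coefficient vector (named numeric)
empty_coeffs <- function() stats::setNames(numeric(0), character(0))

#' Closed-form expansion of a product of two basis matrices
#'
#' Returns the coefficients of Q_rateA %*% Q_rateB in the tree's basis:
#' an empty vector for incomparable vertices (zero product), a single
#' coefficient on the lower rate for comparable distinct vertices, and the
#' exact expansion of the square (obtained by support-cell coefficient
#' extraction from the entrywise closed form) when the two rates coincide.
#' @param tree a `phylosym_tree`
#' @param rateA,rateB non-leaf rate labels
#' @return a named numeric vector of basis coefficients (absent name = 0)
#' @export
product_coeffs <- function(tree, rateA, rateB) {
  stop_if_not_tree(tree)
  u <- rate_vertex(tree, rateA)
  v <- rate_vertex(tree, rateB)
  if (u == v) {
    sq <- square_entrywise(tree, rateA)
    res <- span_coeffs(sq, basis(tree))
    if (!res$in_span) stop("internal error: square not in span")  # Thm 8
    return(res$coeffs)
  }
  rel <- vertex_relation(tree, u, v)$relation
  if (rel == "incomparable") return(empty_coeffs())
  ## orient so that anc is the strict ancestor
  if (rel == "ancestor") {
    anc <- u; dec <- v; lower <- rateB
  } else {
    anc <- v; dec <- u; lower <- rateA
  }
  t_anc <- leaf_count(tree, anc)
  t_child <- leaf_count(tree, child_toward(tree, anc, dec))
  stats::setNames(as.numeric(t_child - t_anc), lower)
}

#' Rebuild a matrix from basis coefficients
#' @param coeffs named numeric vector of coefficients
#' @param basis named list of matrices (e.g. from [basis()])
#' @return the linear combination as a matrix
#' @export
coeffs_to_matrix <- function(coeffs, basis) {
  if (length(basis) == 0L) stop("empty basis", call. = FALSE)
  out <- basis[[1]] * 0
  for (r in names(coeffs)) {
    if (!r %in% names(basis)) stop("unknown basis element: ", r,
                                   call. = FALSE)
    out <- out + coeffs[[r]] * basis[[r]]
  }
  out
}

#' All pairwise product expansions of a tree's basis
#'
#' The structure constants of the phylosymmetric algebra: for every
#' unordered pair of rates, the expansion of the product in the basis.
#' Each expansion is validated against the brute-force matrix product
#' (exact integer equality); the tensor is symmetric because the algebra is
#' commutative.
#' @param tree a `phylosym_tree`
#' @return a list with `rates` and `entries`, the latter a named list keyed
#'   `"a*b"` (rates in preorder order) of coefficient vectors
#' @export
structure_constants <- function(tree) {
  stop_if_not_tree(tree)
  rs <- rates(tree)
  bas <- basis(tree)
  entries <- list()
  for (i in seq_along(rs)) {
    for (j in i:length(rs)) {
      cf <- product_coeffs(tree, rs[i], rs[j])
      prod <- bas[[rs[i]]] %*% bas[[rs[j]]]
      if (!all(coeffs_to_matrix(cf, bas) == prod)) {
        stop("internal error: expansion does not match brute-force product ",
             rs[i], "*", rs[j])
      }
      entries[[paste0(rs[i], "*", rs[j])]] <- cf
    }
  }
  list(rates = rs, entries = entries)
}

#' Exact span-membership test against a disjoint-support basis
#'
#' Because basis matrices have pairwise disjoint off-diagonal supports with
#' entries 1, the only candidate coefficient for each basis element can be
#' read off any one of its off-diagonal support cells; membership holds iff
#' the implied combination reproduces `m` exactly (diagonal included).  No
#' floating-point tolerances are involved.
#' @param m a square matrix in the basis's taxon order
#' @param basis named list of matrices with pairwise disjoint off-diagonal
#'   supports (a tree basis or a merged basis)
#' @return a list: `in_span` (logical), `coeffs` (named vector, zero entries
#'   dropped), and on failure `residual`, the difference between `m` and its
#'   best support-extracted combination
#' @export
span_coeffs <- function(m, basis) {
  coeffs <- numeric(0)
  for (r in names(basis)) {
    b <- basis[[r]]
    off <- which(b != 0 & row(b) != col(b), arr.ind = TRUE)
    if (nrow(off) == 0L) next
    cell <- off[1L, ]
    cf <- m[cell[1L], cell[2L]] / b[cell[1L], cell[2L]]
    if (cf != 0) coeffs[r] <- cf
  }
  approx <- coeffs_to_matrix(coeffs, basis)
  resid <- m - approx
  if (all(resid == 0)) {
    list(in_span = TRUE, coeffs = coeffs, residual = NULL)
  } else {
    list(in_span = FALSE, coeffs = coeffs, residual = resid)
  }
}

## basic sanity of a (possibly merged) basis: symmetric, integer-valued,
## zero row sums, disjoint off-diagonal supports
check_basis_set <- function(basis) {
  if (length(basis) == 0L) return("empty basis")
  seen <- NULL
  for (r in names(basis)) {
    b <- basis[[r]]
    if (!isSymmetric(unname(b))) return(paste0("matrix ", r, " not symmetric"))
    if (any(rowSums(b) != 0)) return(paste0("matrix ", r,
                                            " has nonzero row sums"))
    supp <- which(b != 0 & row(b) != col(b))
    if (length(intersect(supp, seen)) > 0L) {
      return("off-diagonal supports are not disjoint")
    }
    seen <- c(seen, supp)
  }
  TRUE
}

#' Decide whether a matrix set spans an algebra (closure under products)
#'
#' Multiplies every unordered pair (squares included) and tests exact span
#' membership with [span_coeffs()].  Inputs are symmetric with disjoint
#' supports, so unordered pairs suffice: a symmetric product implies the two
#' matrices commute.
#' @param basis_set named list of matrices (a tree basis or the output of
#'   [merge_basis()])
#' @return a `phylosym_closure` list: `closed` (logical) and, when not
#'   closed, `witness` with the offending pair and the residual matrix
#' @export
closure_check <- function(basis_set) {
  chk <- check_basis_set(basis_set)
  if (!isTRUE(chk)) stop("malformed basis: ", chk, call. = FALSE)
  rs <- names(basis_set)
  for (i in seq_along(rs)) {
    for (j in i:length(rs)) {
      prod <- basis_set[[i]] %*% basis_set[[j]]
      res <- span_coeffs(prod, basis_set)
      if (!res$in_span) {
        return(structure(
          list(closed = FALSE,
               witness = list(rateA = rs[i], rateB = rs[j],
                              residual = res$residual)),
          class = "phylosym_closure"))
      }
    }
  }
  structure(list(closed = TRUE, witness = NULL), class = "phylosym_closure")
}

#' @export
print.phylosym_closure <- function(x, ...) {
  if (x$closed) {
    cat("Closed under matrix multiplication: matrix algebra\n")
  } else {
    cat("NOT closed: product", x$witness$rateA, "*", x$witness$rateB,
        "leaves the span\n")
  }
  if (!is.null(x$rationale)) cat("Rationale:", x$rationale, "\n")
  invisible(x)
}

#' Instantiate a numeric rate matrix from a basis
#'
#' Q = sum of value[rate] * Q_rate.  Off-diagonal rates are not forced to be
#' non-negative; `proper` reports whether Q qualifies as a proper rate
#' matrix (all off-diagonal entries >= 0) for downstream modelling.
#' @param basis named list of matrices
#' @param values named numeric vector assigning one value per basis element
#' @return a list: `Q` (numeric matrix) and `proper` (logical)
#' @export
instantiate <- function(basis, values) {
  missing <- setdiff(names(basis), names(values))
  if (length(missing) > 0L) {
    stop("missing rate value for: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  q <- coeffs_to_matrix(values[names(basis)], basis)
  off <- q[row(q) != col(q)]
  list(Q = q, proper = all(off >= 0))
}

#' Transition matrix I + Q of an instantiated rate matrix
#'
#' For a matrix algebra the transition set is the invertible part of
#' I + span, so no matrix exponential is needed.  Invertibility is decided
#' by the determinant of I + Q.
#' @param Q a numeric rate matrix (e.g. `instantiate(...)$Q`)
#' @return a list: `P = I + Q`, `det`, and `invertible`
#' @export
transition_matrix <- function(Q) {
  p <- diag(nrow(Q)) + Q
  dimnames(p) <- dimnames(Q)
  d <- det(p)
  list(P = p, det = d, invertible = abs(d) > 1e-12)
}
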