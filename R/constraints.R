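#' @title Rate-equality constraints and the algebra decision
#' @description
#' Identifying two rates a and b replaces Q_a and Q_b by their sum in the
#' basis.  The merged span is always contained in the unique-rate algebra,
#' but need not itself be closed.  For a single merged pair the outcome is
#' fully characterised by the relative position of the two vertices: the
#' merged set is an algebra iff the vertices are parent and child, or
#' siblings with the same number of leaf descendants.  Two sufficient
#' shortcuts cover broader patterns (connected parent-child chains;
#' equal-size sibling classes); everything else falls back to the generic
#' exact closure check.
#' @name constraints
NULL

#' Construct a partition of a tree's rates into equality classes
#'
#' @param tree a `phylosym_tree`
#' @param classes list of character vectors of rate labels to identify;
#'   rates not mentioned become singleton classes.  Classes must be
#'   pairwise disjoint.
#' @return an object of class `phylosym_rate_classes`: a named list mapping
#'   class label (the members joined by `=`, or the rate itself for
#'   singletons) to its member rates
#' @export
rate_classes <- function(tree, classes = list()) {
  stop_if_not_tree(tree)
  rs <- rates(tree)
  classes <- lapply(classes, as.character)
  flat <- unlist(classes)
  if (anyDuplicated(flat)) stop("rate appears in two classes", call. = FALSE)
  unknown <- setdiff(flat, rs)
  if (length(unknown) > 0L) {
    stop("class references unknown rate: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  classes <- Filter(function(x) length(x) > 0L, classes)
  rest <- setdiff(rs, flat)
  out <- c(classes, as.list(rest))
  ## order members within a class, and classes themselves, by preorder
  out <- lapply(out, function(m) m[order(match(m, rs))])
  out <- out[order(vapply(out, function(m) match(m[1L], rs), integer(1)))]
  names(out) <- vapply(out, paste, character(1), collapse = "=")
  structure(out, class = "phylosym_rate_classes")
}

stop_if_not_classes <- function(tree, classes) {
  if (!inherits(classes, "phylosym_rate_classes")) {
    stop("expected 'phylosym_rate_classes' (see rate_classes())",
         call. = FALSE)
  }
  if (!setequal(unlist(classes), rates(tree))) {
    stop("rate classes do not partition this tree's rates", call. = FALSE)
  }
}

#' Merged basis under a rate-equality partition
#'
#' One matrix per equality class, the sum of the members' basis matrices.
#' Off-diagonal supports remain disjoint, so [span_coeffs()] and
#' [closure_check()] apply unchanged.
#' @param tree a `phylosym_tree`
#' @param classes a `phylosym_rate_classes` partition
#' @return named list of integer matrices, one per class
#' @export
merge_basis <- function(tree, classes) {
  stop_if_not_tree(tree)
  stop_if_not_classes(tree, classes)
  bas <- basis(tree)
  out <- lapply(classes, function(members) {
    Reduce(`+`, bas[members])
  })
  names(out) <- names(classes)
  out
}

#' Classify a pair of internal vertices into the five merge configurations
#'
#' The five exhaustive configurations for distinct internal vertices u, v,
#' determining whether identifying their rates yields an algebra:
#' \describe{
#'   \item{1}{comparable with a vertex strictly between them -- not closed}
#'   \item{2}{incomparable and not siblings -- not closed}
#'   \item{3}{siblings with different leaf counts -- not closed}
#'   \item{4}{siblings with equal leaf counts -- closed}
#'   \item{5}{parent and child -- closed}
#' }
#' @param tree a `phylosym_tree`
#' @param u,v distinct non-leaf vertex ids
#' @return a list: `case` (integer 1-5), `algebra` (logical), `description`
#' @export
classify_pair <- function(tree, u, v) {
  stop_if_not_tree(tree)
  if (u == v) stop("vertices must be distinct", call. = FALSE)
  if (is_leaf(tree, u) || is_leaf(tree, v)) {
    stop("both vertices must be non-leaf", call. = FALSE)
  }
  rel <- vertex_relation(tree, u, v)
  parent_child <- (!is.na(tree$parent[u]) && tree$parent[u] == v) ||
    (!is.na(tree$parent[v]) && tree$parent[v] == u)
  if (parent_child) {
    case <- 5L; desc <- "parent and child"
  } else if (rel$siblings) {
    if (leaf_count(tree, u) == leaf_count(tree, v)) {
      case <- 4L; desc <- "siblings with equal leaf counts"
    } else {
      case <- 3L; desc <- "siblings with unequal leaf counts"
    }
  } else if (rel$relation %in% c("ancestor", "descendant")) {
    case <- 1L; desc <- "comparable with an intermediate vertex"
  } else {
    case <- 2L; desc <- "incomparable, not siblings"
  }
  list(case = case, algebra = case %in% c(4L, 5L), description = desc)
}

#' Connected-identification sufficient condition
#'
#' `TRUE` when every non-singleton equality class induces a connected
#' subgraph of the tree (a union of parent-child chains).  Identifying the
#' rates along such chains contracts edges one at a time, each step yielding
#' the algebra of a smaller tree, so the merged basis is an algebra.
#' @param tree a `phylosym_tree`
#' @param classes a `phylosym_rate_classes` partition
#' @return logical
#' @export
connected_identification_check <- function(tree, classes) {
  stop_if_not_tree(tree)
  stop_if_not_classes(tree, classes)
  for (members in classes) {
    if (length(members) == 1L) next
    vs <- vapply(members, function(r) rate_vertex(tree, r), integer(1))
    ## connectivity of the induced subgraph under tree (parent) edges
    comp <- seq_along(vs)
    for (i in seq_along(vs)) {
      p <- tree$parent[vs[i]]
      j <- match(p, vs)
      if (!is.na(j)) comp[comp == comp[i]] <- comp[j]
    }
    if (length(unique(comp)) > 1L) return(FALSE)
  }
  TRUE
}

#' Decide whether a constrained rate pattern still yields a matrix algebra
#'
#' Applies, in order: the exact five-case characterisation when exactly one
#' class of size two is merged; the equal-size-sibling and connected
#' parent-child sufficient conditions; otherwise the generic exact closure
#' check on the merged basis.  Whenever a theorem-based shortcut fires, the
#' generic check is still run and cross-validated against it.
#' @param tree a `phylosym_tree`
#' @param classes a `phylosym_rate_classes` partition
#' @return a `phylosym_closure` with an added `rationale` string and, when
#'   the five-case characterisation applies, `case`
#' @export
decide_algebra <- function(tree, classes) {
  stop_if_not_tree(tree)
  stop_if_not_classes(tree, classes)
  merged <- merge_basis(tree, classes)
  generic <- closure_check(merged)
  nonsing <- Filter(function(m) length(m) > 1L, classes)

  rationale <- "generic closure check"
  case <- NULL
  if (length(nonsing) == 0L) {
    rationale <- "unique rates: phylosymmetric algebra"
    if (!generic$closed) stop("internal error: unique-rate basis not closed")
  } else if (length(nonsing) == 1L && length(nonsing[[1]]) == 2L) {
    pair <- vapply(nonsing[[1]], function(r) rate_vertex(tree, r),
                   integer(1))
    pv <- classify_pair(tree, pair[1L], pair[2L])
    if (pv$algebra != generic$closed) {
      stop("internal error: five-case characterisation disagrees with ",
           "generic closure check")
    }
    case <- pv$case
    rationale <- paste0("single merged pair, case ", pv$case, " (",
                        pv$description, ")")
  } else if (length(nonsing) == 1L &&
               all_equal_size_siblings(tree, nonsing)) {
    rationale <- "equal-size sibling class (sufficient condition)"
    if (!generic$closed) stop("internal error: sibling shortcut disagrees")
  } else if (connected_identification_check(tree, classes)) {
    rationale <- "connected parent-child identification (sufficient condition)"
    if (!generic$closed) stop("internal error: connectivity shortcut disagrees")
  }
  generic$rationale <- rationale
  generic$case <- case
  generic
}

## TRUE when every non-singleton class consists of pairwise siblings with a
## common leaf count.  Only applied to a single merged class: two such
## classes can interact through cross products with unequal coefficients.
all_equal_size_siblings <- function(tree, nonsing) {
  for (members in nonsing) {
    vs <- vapply(members, function(r) rate_vertex(tree, r), integer(1))
    par <- tree$parent[vs]
    if (anyNA(par) || length(unique(par)) != 1L) return(FALSE)
    if (length(unique(vapply(vs, function(v) leaf_count(tree, v),
                             integer(1)))) != 1L) {
      return(FALSE)
    }
  }
  length(nonsing) > 0L
}

#' Number of free parameters of a constrained model
#'
#' One free rate per equality class.  A binary tree on n leaves with unique
#' rates has n - 1 internal vertices and hence n - 1 parameters; equality
#' constraints reduce the count (K2P on 4 states has 2).
#' @param tree a `phylosym_tree`
#' @param classes a `phylosym_rate_classes` partition
#' @return integer
#' @export
parameter_count <- function(tree, classes = rate_classes(tree)) {
  stop_if_not_tree(tree)
  stop_if_not_classes(tree, classes)
  length(classes)
}

#' @export
print.phylosym_rate_classes <- function(x, ...) {
  cat("Rate equality classes:\n")
  for (nm in names(x)) {
    cat("  ", nm, if (length(x[[nm]]) > 1L) "  (merged)" else "", "\n",
        sep = "")
  }
  invisible(x)
}
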