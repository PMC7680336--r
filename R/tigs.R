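#' @title Tree-induced graph sets and mrca graphs
#' @description
#' Each rate a of a tree defines an undirected graph G_a on the taxon set
#' with an edge (x, y) iff mrca(x, y) carries rate a.  Its non-isolated part
#' is complete multipartite with parts the child clusters of the rate's
#' vertex, and the basis matrix satisfies Q_a = -L(G_a) where L is the graph
#' Laplacian.  The collection over all rates is a tree-induced graph set
#' (TIGS): edge-disjoint graphs covering the complete graph, each a complete
#' multipartite component plus isolated vertices, with a recursive condition
#' tying every multi-element part to the support of exactly one other graph.
#' TIGS on X are in bijection with hierarchies on X.
#' @name tigs
NULL

## normalize an edge list to a 2-column character matrix of unordered pairs
## in canonical vertex order, sorted, deduplicated
normalize_edges <- function(edges, vertices) {
  if (is.null(edges) || NROW(edges) == 0L) {
    return(matrix(character(0), ncol = 2))
  }
  edges <- matrix(as.character(edges), ncol = 2)
  i <- match(edges[, 1], vertices)
  j <- match(edges[, 2], vertices)
  if (anyNA(i) || anyNA(j)) stop("edge endpoint not in vertex set",
                                 call. = FALSE)
  if (any(i == j)) stop("self-loop in edge list", call. = FALSE)
  lo <- pmin(i, j); hi <- pmax(i, j)
  m <- unique(cbind(lo, hi))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  cbind(vertices[m[, 1]], vertices[m[, 2]])
}

#' Construct a labelled graph on a taxon set
#' @param vertices character vector of vertex (taxon) names
#' @param edges two-column matrix (or data frame) of unordered vertex pairs
#' @param rate optional rate label attached to the graph
#' @return an object of class `phylosym_graph`
#' @export
labeled_graph <- function(vertices, edges = NULL, rate = NULL) {
  vertices <- as.character(vertices)
  if (anyDuplicated(vertices)) stop("duplicate vertices", call. = FALSE)
  structure(
    list(vertices = vertices,
         edges = normalize_edges(edges, vertices),
         rate = rate),
    class = "phylosym_graph"
  )
}

#' Adjacency matrix of a labelled graph
#' @param g a `phylosym_graph`
#' @return symmetric 0/1 integer matrix in the graph's vertex order
#' @export
adjacency <- function(g) {
  a <- zero_matrix(g$vertices)
  if (nrow(g$edges) > 0L) {
    a[g$edges] <- 1L
    a[g$edges[, c(2, 1), drop = FALSE]] <- 1L
  }
  a
}

#' Degree matrix of a labelled graph
#' @param g a `phylosym_graph`
#' @return diagonal integer matrix of vertex degrees
#' @export
degree_matrix <- function(g) {
  a <- adjacency(g)
  d <- zero_matrix(g$vertices)
  diag(d) <- as.integer(rowSums(a))
  d
}

#' Graph Laplacian L = D - A
#'
#' Symmetric, zero row sums, -1 at every edge.  For a rate's mrca graph the
#' negative Laplacian is exactly the basis matrix of that rate.
#' @param g a `phylosym_graph`
#' @return integer matrix
#' @export
laplacian <- function(g) {
  degree_matrix(g) - adjacency(g)
}

#' The mrca graph of one rate
#' @param tree a `phylosym_tree`
#' @param rate a non-leaf rate label
#' @return a `phylosym_graph` on the canonical taxon order whose non-isolated
#'   part is complete k-partite with parts the child clusters of the rate's
#'   vertex
#' @export
mrca_graph <- function(tree, rate) {
  stop_if_not_tree(tree)
  u <- rate_vertex(tree, rate)
  parts <- lapply(tree$children[[u]], function(w) cluster_of(tree, w))
  edges <- NULL
  k <- length(parts)
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      edges <- rbind(edges, as.matrix(expand.grid(parts[[i]], parts[[j]],
                                                  stringsAsFactors = FALSE)))
    }
  }
  labeled_graph(taxa(tree), edges, rate = rate)
}

#' The tree-induced graph set of a tree
#' @param tree a `phylosym_tree`
#' @return an object of class `phylosym_tigs`: a list of `phylosym_graph`s,
#'   one per non-leaf vertex, keyed by rate
#' @export
tigs_of_tree <- function(tree) {
  stop_if_not_tree(tree)
  rs <- rates(tree)
  gs <- lapply(rs, function(r) mrca_graph(tree, r))
  names(gs) <- rs
  structure(list(graphs = gs, taxa = taxa(tree)), class = "phylosym_tigs")
}

#' Construct a TIGS object from raw graphs
#' @param graphs list of `phylosym_graph`s on a common vertex set
#' @return a `phylosym_tigs` (not validated; see [validate_tigs()])
#' @export
tigs_set <- function(graphs) {
  if (length(graphs) == 0L) stop("empty graph set", call. = FALSE)
  tx <- graphs[[1]]$vertices
  for (g in graphs) {
    if (!identical(g$vertices, tx)) {
      stop("graphs must share a common vertex set (same order)",
           call. = FALSE)
    }
  }
  structure(list(graphs = graphs, taxa = tx), class = "phylosym_tigs")
}

## support = vertices of nonzero degree
graph_support <- function(g) {
  if (nrow(g$edges) == 0L) return(character(0))
  g$vertices[g$vertices %in% c(g$edges)]
}

## parts of the complete multipartite component: equivalence classes of
## non-adjacency on the support.  Returns NULL if the support is not a
## complete multipartite graph.
multipartite_parts <- function(g) {
  s <- graph_support(g)
  if (length(s) == 0L) return(list())
  a <- adjacency(g)[s, s, drop = FALSE]
  ## group vertices by identical adjacency rows: in a complete multipartite
  ## graph two vertices are in the same part iff they have the same
  ## neighbourhood
  key <- apply(a, 1, paste, collapse = "")
  parts <- split(s, key)
  names(parts) <- NULL
  ## verify: within a part no edges, across parts all edges
  for (i in seq_along(parts)) {
    if (any(a[parts[[i]], parts[[i]]] != 0L)) return(NULL)
    for (j in seq_along(parts)) {
      if (i != j && any(a[parts[[i]], parts[[j]]] != 1L)) return(NULL)
    }
  }
  parts
}

#' Validate the four defining conditions of a tree-induced graph set
#'
#' Checks, in order: (1) pairwise edge-disjointness; (2) the union of the
#' edge sets is the complete graph on the common vertex set; (3) every graph
#' is a set of isolated vertices plus one complete multipartite component,
#' with exactly one graph free of isolated vertices; (4) every part with
#' more than one element of any graph's partition is the support of exactly
#' one other graph.
#' @param g a `phylosym_tigs`
#' @return a list with `valid` (logical) and, on failure, `violation` naming
#'   the first condition that fails
#' @export
validate_tigs <- function(g) {
  if (!inherits(g, "phylosym_tigs")) stop("expected a 'phylosym_tigs'",
                                          call. = FALSE)
  gs <- g$graphs
  tx <- g$taxa
  fail <- function(msg) list(valid = FALSE, violation = msg)

  edge_key <- function(gr) {
    if (nrow(gr$edges) == 0L) return(character(0))
    paste(gr$edges[, 1], gr$edges[, 2], sep = "\r")
  }
  all_edges <- unlist(lapply(gs, edge_key))
  if (anyDuplicated(all_edges)) {
    return(fail("edge sets are not pairwise disjoint"))
  }
  n <- length(tx)
  if (length(all_edges) != n * (n - 1L) / 2L) {
    return(fail("union of edge sets is not the complete graph"))
  }

  parts_of <- vector("list", length(gs))
  n_full <- 0L
  for (i in seq_along(gs)) {
    p <- multipartite_parts(gs[[i]])
    if (is.null(p) || length(p) == 1L) {
      return(fail(
        "graph is not isolated vertices plus a complete k-partite component"))
    }
    parts_of[[i]] <- p
    if (length(graph_support(gs[[i]])) == n) n_full <- n_full + 1L
  }
  if (n_full != 1L) {
    return(fail("there must be exactly one graph with no isolated vertices"))
  }

  supports <- lapply(gs, function(gr) sort(graph_support(gr)))
  sup_keys <- vapply(supports, paste, character(1), collapse = "\r")
  for (i in seq_along(gs)) {
    for (p in parts_of[[i]]) {
      if (length(p) > 1L) {
        hits <- sum(sup_keys == paste(sort(p), collapse = "\r"))
        if (hits != 1L) {
          return(fail(paste0("part {", paste(p, collapse = ","),
                             "} is the support of ", hits,
                             " graphs (need exactly 1)")))
        }
      }
    }
  }
  list(valid = TRUE, violation = NULL)
}

#' Map a hierarchy to its tree-induced graph set
#'
#' For each non-singleton cluster A with inclusion-maximal proper
#' subclusters A_1, ..., A_k, the associated graph is the complement (within
#' A) of the disjoint union of complete graphs on the A_i -- i.e. the
#' complete k-partite graph with parts A_i -- together with the taxa outside
#' A as isolated vertices.
#' @param h a `phylosym_hierarchy`
#' @return a `phylosym_tigs`
#' @export
hierarchy_to_tigs <- function(h) {
  v <- validate_hierarchy(h)
  if (!isTRUE(v)) stop("invalid hierarchy: ", v, call. = FALSE)
  cl <- h$clusters
  nonsing <- cl[lengths(cl) > 1L]
  gs <- lapply(nonsing, function(A) {
    subs <- cl[vapply(cl, function(s) {
      length(s) < length(A) && all(s %in% A)
    }, logical(1))]
    ## inclusion-maximal among the proper subclusters of A
    maximal <- subs[vapply(seq_along(subs), function(i) {
      !any(vapply(seq_along(subs), function(j) {
        j != i && length(subs[[j]]) > length(subs[[i]]) &&
          all(subs[[i]] %in% subs[[j]])
      }, logical(1)))
    }, logical(1))]
    edges <- NULL
    k <- length(maximal)
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        edges <- rbind(edges,
                       as.matrix(expand.grid(maximal[[i]], maximal[[j]],
                                             stringsAsFactors = FALSE)))
      }
    }
    labeled_graph(h$taxa, edges)
  })
  tigs_set(gs)
}

#' Recover the hierarchy of a tree-induced graph set
#'
#' Clusters are the supports of the graphs' multipartite components' parts,
#' plus X and all singletons; inverse of [hierarchy_to_tigs()].
#' @param g a `phylosym_tigs`
#' @return a `phylosym_hierarchy`
#' @export
tigs_to_hierarchy <- function(g) {
  chk <- validate_tigs(g)
  if (!chk$valid) stop("invalid TIGS: ", chk$violation, call. = FALSE)
  parts <- unlist(lapply(g$graphs, multipartite_parts), recursive = FALSE)
  hierarchy(g$taxa, parts)
}

#' @export
print.phylosym_graph <- function(x, ...) {
  cat("Graph on", length(x$vertices), "vertices")
  if (!is.null(x$rate)) cat(" (rate ", x$rate, ")", sep = "")
  cat(":", nrow(x$edges), "edges\n")
  if (nrow(x$edges) > 0L) {
    cat(" ", paste(x$edges[, 1], x$edges[, 2], sep = "-", collapse = " "),
        "\n")
  }
  invisible(x)
}

#' @export
print.phylosym_tigs <- function(x, ...) {
  cat("Tree-induced graph set:", length(x$graphs), "graphs on {",
      paste(x$taxa, collapse = ","), "}\n")
  for (g in x$graphs) print(g)
  invisible(x)
}
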