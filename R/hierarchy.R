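#' @title Hierarchies (laminar families) of taxon subsets
#' @description
#' A hierarchy on a taxon set X is a collection of subsets of X containing X
#' itself and every singleton, in which any two members are either disjoint
#' or nested.  Hierarchies are exactly the cluster sets of rooted trees, and
#' [clusters()] / [tree_from_hierarchy()] realise the two directions of that
#' equivalence.
#' @name hierarchy
NULL

#' Construct a hierarchy object
#'
#' @param taxa character vector of taxon names (canonical order)
#' @param clusters list of character vectors, each a subset of `taxa`.  X and
#'   the singletons are added automatically if missing.
#' @param validate check the laminar-family invariants (default `TRUE`)
#' @return an object of class `phylosym_hierarchy`
#' @export
hierarchy <- function(taxa, clusters = list(), validate = TRUE) {
  taxa <- as.character(taxa)
  cl <- lapply(clusters, function(s) taxa[sort(match(s, taxa))])
  cl <- c(cl, list(taxa), lapply(taxa, identity))
  cl <- unique(cl)
  h <- structure(list(taxa = taxa, clusters = cl),
                 class = "phylosym_hierarchy")
  if (validate) {
    v <- validate_hierarchy(h)
    if (!isTRUE(v)) stop(v, call. = FALSE)
  }
  h
}

#' Validate the laminar-family invariants of a hierarchy
#' @param h a `phylosym_hierarchy`
#' @return `TRUE`, or a character message naming the first violation
#' @export
validate_hierarchy <- function(h) {
  if (!inherits(h, "phylosym_hierarchy")) return("not a hierarchy object")
  cl <- h$clusters
  if (any(vapply(cl, function(s) !all(s %in% h$taxa), logical(1)))) {
    return("cluster contains unknown taxon")
  }
  keyed <- vapply(cl, function(s) paste(sort(s), collapse = "\r"),
                  character(1))
  if (anyDuplicated(keyed)) return("duplicate clusters")
  if (!paste(sort(h$taxa), collapse = "\r") %in% keyed) {
    return("missing full taxon set X")
  }
  if (!all(h$taxa %in% keyed)) return("missing singleton cluster")
  for (i in seq_along(cl)) {
    for (j in seq_len(i - 1L)) {
      a <- cl[[i]]; b <- cl[[j]]
      inter <- intersect(a, b)
      if (length(inter) > 0L && length(inter) < min(length(a), length(b))) {
        return(paste0("clusters {", paste(a, collapse = ","), "} and {",
                      paste(b, collapse = ","), "} overlap without nesting"))
      }
    }
  }
  TRUE
}

#' Cluster set of a rooted tree
#'
#' One cluster per vertex: the set of leaf descendants.  The root
#' contributes X and each leaf its own singleton, so the result is a
#' hierarchy with exactly as many clusters as the tree has vertices.
#' @param tree a `phylosym_tree`
#' @return a `phylosym_hierarchy`
#' @export
clusters <- function(tree) {
  stop_if_not_tree(tree)
  cl <- lapply(vertices(tree), function(v) cluster_of(tree, v))
  hierarchy(taxa(tree), cl, validate = FALSE)
}

#' Build the rooted tree whose cluster set is a given hierarchy
#'
#' Inverse of [clusters()] up to vertex relabelling: internal vertices get
#' auto-generated rate names `r1`, `r2`, ... in preorder.
#' @param h a `phylosym_hierarchy`
#' @return a `phylosym_tree`
#' @export
tree_from_hierarchy <- function(h) {
  v <- validate_hierarchy(h)
  if (!isTRUE(v)) stop("invalid hierarchy: ", v, call. = FALSE)
  cl <- h$clusters
  sizes <- lengths(cl)
  ## parent of a cluster = smallest strictly-containing cluster
  n <- length(cl)
  parent <- rep(NA_integer_, n)
  for (i in seq_len(n)) {
    sup <- which(sizes > sizes[i] &
                   vapply(cl, function(s) all(cl[[i]] %in% s), logical(1)))
    if (length(sup) > 0L) parent[i] <- sup[which.min(sizes[sup])]
  }
  children <- vector("list", n)
  for (i in seq_len(n)) children[[i]] <- integer(0)
  for (i in seq_len(n)) {
    if (!is.na(parent[i])) {
      children[[parent[i]]] <- c(children[[parent[i]]], i)
    }
  }
  ## order children by first appearance of their taxa in canonical order
  for (i in seq_len(n)) {
    if (length(children[[i]]) > 1L) {
      first <- vapply(children[[i]],
                      function(j) min(match(cl[[j]], h$taxa)), numeric(1))
      children[[i]] <- children[[i]][order(first)]
    }
  }
  taxon <- rep(NA_character_, n)
  leaf <- lengths(children) == 0L
  taxon[leaf] <- vapply(cl[leaf], identity, character(1))
  root <- which(is.na(parent))
  rate <- rep(NA_character_, n)
  ord <- preorder_ids(parent, children, root)
  k <- 0L
  for (vtx in ord) {
    if (!leaf[vtx]) {
      k <- k + 1L
      rate[vtx] <- paste0("r", k)
    }
  }
  tr <- new_rooted_tree(parent, children, taxon, rate, h$taxa)
  bad <- which(!leaf & lengths(children) < 2L)
  if (length(bad) > 0L) stop("invalid hierarchy: produced degree-2 vertex",
                             call. = FALSE)
  tr
}

## order-independent equality of two hierarchies (same cluster sets)
hierarchy_equal <- function(h1, h2) {
  key <- function(h) sort(vapply(h$clusters,
                                 function(s) paste(sort(s), collapse = "\r"),
                                 character(1)))
  setequal(h1$taxa, h2$taxa) && identical(key(h1), key(h2))
}

#' Serialize a hierarchy to JSON (list of taxon lists)
#' @param h a `phylosym_hierarchy`
#' @param path optional file path; if `NULL` the JSON string is returned
#' @return JSON string (invisibly, if written to file)
#' @export
hierarchy_to_json <- function(h, path = NULL) {
  js <- jsonlite::toJSON(list(taxa = h$taxa, clusters = h$clusters))
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a hierarchy from its JSON form
#' @param path file path or JSON string
#' @return a `phylosym_hierarchy`
#' @export
hierarchy_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  hierarchy(x$taxa, as.list(x$clusters))
}

#' @export
print.phylosym_hierarchy <- function(x, ...) {
  cat("Hierarchy on {", paste(x$taxa, collapse = ","), "} with",
      length(x$clusters), "clusters\n")
  nontriv <- Filter(function(s) length(s) > 1L && length(s) < length(x$taxa),
                    x$clusters)
  for (s in nontriv) cat("  {", paste(s, collapse = ","), "}\n")
  invisible(x)
}
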