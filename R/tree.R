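#' @title Rooted trees with rate-labelled internal vertices
#' @description
#' The central data structure: a rooted tree whose leaves are bijectively
#' labelled by a taxon (state) set and whose non-leaf vertices each carry a
#' symbolic rate label.  Every non-leaf vertex, the root included, must have
#' at least two children; degree-2 vertices are rejected as malformed.  Rate
#' labels are text symbols, not numbers: numeric instantiation is a separate
#' step (see [instantiate()]).
#'
#' Internally a tree is a list of parallel vectors indexed by vertex id
#' (integers `1..n_vertices`): `parent` (NA at the root), `children` (list of
#' integer vectors, in order), `taxon` (leaf labels, NA for non-leaves) and
#' `rate` (NA for leaves).  `taxa` records the canonical taxon order used for
#' all matrix rows/columns.
#' @name rooted-tree
NULL

new_rooted_tree <- function(parent, children, taxon, rate, taxa) {
  structure(
    list(
      n_vertices = length(parent),
      root = which(is.na(parent)),
      parent = parent,
      children = children,
      taxon = taxon,
      rate = rate,
      taxa = taxa
    ),
    class = "phylosym_tree"
  )
}

#' Test whether an object is a phylosym rooted tree
#' @param x object to test
#' @return logical scalar
#' @export
is_rooted_tree <- function(x) inherits(x, "phylosym_tree")

stop_if_not_tree <- function(tree) {
  if (!is_rooted_tree(tree)) {
    stop("expected a 'phylosym_tree' (see parse_newick())", call. = FALSE)
  }
}

#' Parse a Newick string into a rooted tree
#'
#' Internal vertex labels name rates; unlabelled internal vertices receive
#' auto-generated unique rate names (`r1`, `r2`, ... in preorder).  Branch
#' lengths, if present, are parsed and discarded with a warning: in this
#' model rates live on vertices, not edges.  The leaf order of first
#' appearance in the string is recorded and used as the canonical matrix
#' row/column order unless `sort_taxa = TRUE` forces lexicographic order.
#'
#' @param text a Newick string (must end in `;`)
#' @param sort_taxa if `TRUE`, canonical taxon order is lexicographic rather
#'   than order of first appearance
#' @param dup_rates what to do when two internal vertices carry the same
#'   label: `"error"` (default) rejects the input; `"merge"` renames the
#'   duplicates to unique labels and records the intended equality classes in
#'   `attr(tree, "rate_classes")` for use with the constraint machinery
#' @return a `phylosym_tree`
#' @examples
#' tr <- parse_newick("((1,2)beta,(3,(4,5)delta)gamma)alpha;")
#' taxa(tr)
#' rates(tr)
#' @seealso [write_newick()], [clusters()], [basis()]
#' @export
parse_newick <- function(text, sort_taxa = FALSE,
                         dup_rates = c("error", "merge")) {
  dup_rates <- match.arg(dup_rates)
  ph <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse failure: ", conditionMessage(e),
                             call. = FALSE),
    warning = function(w) stop("Newick parse failure: ", conditionMessage(w),
                               call. = FALSE)
  )
  if (is.null(ph) || !inherits(ph, "phylo")) {
    stop("Newick parse failure: not a single rooted tree", call. = FALSE)
  }
  if (!is.null(ph$edge.length)) {
    warning("branch lengths present in Newick input are ignored ",
            "(rates live on vertices, not edges)", call. = FALSE)
  }
  from_phylo(ph, sort_taxa = sort_taxa, dup_rates = dup_rates)
}

## Convert an ape 'phylo' (tips numbered in order of appearance) into the
## validated internal representation.
from_phylo <- function(ph, sort_taxa = FALSE, dup_rates = "error") {
  ntip <- length(ph$tip.label)
  nvert <- ntip + ph$Nnode
  parent <- rep(NA_integer_, nvert)
  children <- vector("list", nvert)
  for (i in seq_len(nvert)) children[[i]] <- integer(0)
  for (k in seq_len(nrow(ph$edge))) {
    p <- ph$edge[k, 1L]; c <- ph$edge[k, 2L]
    parent[c] <- p
    children[[p]] <- c(children[[p]], c)
  }
  is_leaf <- seq_len(nvert) <= ntip
  nchild <- lengths(children)
  if (any(is_leaf & nchild > 0L)) stop("malformed tree", call. = FALSE)
  root <- which(is.na(parent))
  if (length(root) != 1L) stop("Newick parse failure: no unique root",
                               call. = FALSE)
  single <- which(!is_leaf & nchild < 2L)
  if (length(single) > 0L) {
    if (any(single == root)) {
      stop("malformed tree: root must have at least two children",
           call. = FALSE)
    }
    stop("malformed tree: internal vertex with exactly one child",
         call. = FALSE)
  }
  if (anyDuplicated(ph$tip.label)) {
    stop("duplicate leaf labels: ",
         paste(unique(ph$tip.label[duplicated(ph$tip.label)]),
               collapse = ", "), call. = FALSE)
  }
  taxon <- rep(NA_character_, nvert)
  taxon[seq_len(ntip)] <- ph$tip.label

  rate <- rep(NA_character_, nvert)
  labs <- ph$node.label
  if (is.null(labs)) labs <- rep("", ph$Nnode)
  labs[is.na(labs)] <- ""
  rate[(ntip + 1L):nvert] <- labs
  ## auto-name unlabelled internal vertices, in preorder, avoiding clashes
  taken <- setdiff(unique(rate), c(NA, ""))
  auto <- 0L
  ord <- preorder_ids(parent, children, root)
  for (v in ord) {
    if (!is_leaf[v] && !is.na(rate[v]) && rate[v] == "") {
      repeat {
        auto <- auto + 1L
        cand <- paste0("r", auto)
        if (!cand %in% taken) break
      }
      rate[v] <- cand
      taken <- c(taken, cand)
    }
  }
  rate_classes <- NULL
  internal_rates <- rate[!is_leaf]
  if (anyDuplicated(internal_rates)) {
    if (dup_rates == "error") {
      stop("duplicate internal rate labels: ",
           paste(unique(internal_rates[duplicated(internal_rates)]),
                 collapse = ", "),
           "; re-parse with dup_rates = \"merge\" to treat them as an ",
           "equality constraint", call. = FALSE)
    }
    ## rename duplicates uniquely, remember intended classes
    base <- rate
    seen <- character(0)
    groups <- split(ord[!is_leaf[ord]], rate[ord[!is_leaf[ord]]])
    for (v in ord) {
      if (is_leaf[v]) next
      if (rate[v] %in% seen) {
        k <- 1L
        repeat {
          k <- k + 1L
          cand <- paste0(base[v], ".", k)
          if (!cand %in% c(seen, base)) break
        }
        rate[v] <- cand
      }
      seen <- c(seen, rate[v])
    }
    rate_classes <- lapply(groups, function(vs) rate[vs])
    names(rate_classes) <- NULL
  }

  taxa <- if (sort_taxa) sort(ph$tip.label) else ph$tip.label
  tr <- new_rooted_tree(parent, children, taxon, rate, taxa)
  if (!is.null(rate_classes)) {
    attr(tr, "rate_classes") <- rate_classes(tr, rate_classes)
  }
  tr
}

preorder_ids <- function(parent, children, root) {
  out <- integer(0)
  stack <- root
  while (length(stack) > 0L) {
    v <- stack[1L]; stack <- stack[-1L]
    out <- c(out, v)
    stack <- c(children[[v]], stack)
  }
  out
}

#' Write a rooted tree as a Newick string
#'
#' Internal labels are the rate names; no branch lengths are emitted.
#' @param tree a `phylosym_tree`
#' @return a Newick string ending in `;`
#' @export
write_newick <- function(tree) {
  stop_if_not_tree(tree)
  rec <- function(v) {
    if (is_leaf(tree, v)) return(tree$taxon[v])
    inner <- vapply(tree$children[[v]], rec, character(1))
    paste0("(", paste(inner, collapse = ","), ")", tree$rate[v])
  }
  paste0(rec(tree$root), ";")
}

#' Canonical taxon order of a tree
#' @param tree a `phylosym_tree`
#' @return character vector of taxon names in canonical (matrix) order
#' @export
taxa <- function(tree) {
  stop_if_not_tree(tree)
  tree$taxa
}

#' Rate labels of a tree's non-leaf vertices
#' @param tree a `phylosym_tree`
#' @return character vector of rate labels, in preorder
#' @export
rates <- function(tree) {
  stop_if_not_tree(tree)
  ord <- preorder_ids(tree$parent, tree$children, tree$root)
  ord <- ord[!vapply(ord, function(v) is_leaf(tree, v), logical(1))]
  tree$rate[ord]
}

#' Vertices of a tree
#' @param tree a `phylosym_tree`
#' @return integer vertex ids
#' @export
vertices <- function(tree) seq_len(tree$n_vertices)

#' Internal (non-leaf) vertex ids of a tree, in preorder
#' @param tree a `phylosym_tree`
#' @return integer vertex ids
#' @export
internal_vertices <- function(tree) {
  stop_if_not_tree(tree)
  ord <- preorder_ids(tree$parent, tree$children, tree$root)
  ord[lengths(tree$children[ord]) > 0L]
}

is_leaf <- function(tree, v) length(tree$children[[v]]) == 0L

#' Look up the vertex carrying a given rate label
#' @param tree a `phylosym_tree`
#' @param rate a rate label
#' @return integer vertex id
#' @export
rate_vertex <- function(tree, rate) {
  stop_if_not_tree(tree)
  v <- which(!is.na(tree$rate) & tree$rate == rate)
  if (length(v) != 1L) stop("unknown rate label: ", rate, call. = FALSE)
  v
}

#' Look up the leaf vertex for a taxon
#' @param tree a `phylosym_tree`
#' @param x a taxon name
#' @return integer vertex id
#' @export
taxon_vertex <- function(tree, x) {
  stop_if_not_tree(tree)
  v <- which(!is.na(tree$taxon) & tree$taxon == x)
  if (length(v) != 1L) stop("unknown taxon: ", x, call. = FALSE)
  v
}

ancestors_of <- function(tree, v) {
  ## v first, then its parent chain up to the root (a vertex is its own
  ## ancestor)
  out <- v
  while (!is.na(tree$parent[v])) {
    v <- tree$parent[v]
    out <- c(out, v)
  }
  out
}

#' Most recent common ancestor of two taxa
#'
#' A vertex is an ancestor (and descendant) of itself, so `mrca(tree, x, x)`
#' is the leaf carrying `x`.
#' @param tree a `phylosym_tree`
#' @param x,y taxon names
#' @return integer vertex id of the mrca
#' @export
mrca <- function(tree, x, y) {
  stop_if_not_tree(tree)
  a <- ancestors_of(tree, taxon_vertex(tree, x))
  b <- ancestors_of(tree, taxon_vertex(tree, y))
  a[match(TRUE, a %in% b)]
}

#' Relation between two vertices of a tree
#'
#' Classifies an ordered vertex pair as `"equal"`, `"ancestor"` (u is a
#' strict ancestor of v), `"descendant"`, or `"incomparable"`, and reports
#' whether the two vertices are siblings (share a parent).
#' @param tree a `phylosym_tree`
#' @param u,v vertex ids
#' @return a list with components `relation` and `siblings`
#' @export
vertex_relation <- function(tree, u, v) {
  stop_if_not_tree(tree)
  if (!u %in% vertices(tree) || !v %in% vertices(tree)) {
    stop("unknown vertex", call. = FALSE)
  }
  rel <- if (u == v) {
    "equal"
  } else if (u %in% ancestors_of(tree, v)) {
    "ancestor"
  } else if (v %in% ancestors_of(tree, u)) {
    "descendant"
  } else {
    "incomparable"
  }
  sib <- u != v && !is.na(tree$parent[u]) && !is.na(tree$parent[v]) &&
    tree$parent[u] == tree$parent[v]
  list(relation = rel, siblings = sib)
}

#' Number of leaf descendants of a vertex
#' @param tree a `phylosym_tree`
#' @param u vertex id
#' @return integer count (1 for a leaf)
#' @export
leaf_count <- function(tree, u) {
  length(cluster_of(tree, u))
}

## taxa below vertex u, in canonical order
cluster_of <- function(tree, u) {
  stop_if_not_tree(tree)
  if (!u %in% vertices(tree)) stop("unknown vertex", call. = FALSE)
  if (is_leaf(tree, u)) return(tree$taxon[u])
  out <- unlist(lapply(tree$children[[u]], function(w) cluster_of(tree, w)))
  tree$taxa[sort(match(out, tree$taxa))]
}

#' The child of a vertex on the path toward a strict descendant
#' @param tree a `phylosym_tree`
#' @param u vertex id
#' @param v a strict descendant of `u`
#' @return integer vertex id of the unique child of `u` that is an ancestor
#'   of `v`
#' @export
child_toward <- function(tree, u, v) {
  stop_if_not_tree(tree)
  anc <- ancestors_of(tree, v)
  i <- match(u, anc)
  if (is.na(i) || i == 1L) {
    stop("vertex is not a strict descendant", call. = FALSE)
  }
  anc[i - 1L]
}

#' @export
print.phylosym_tree <- function(x, ...) {
  cat("Rooted tree on", length(x$taxa), "taxa:",
      paste(x$taxa, collapse = ", "), "\n")
  cat("Rates:", paste(rates(x), collapse = ", "), "\n")
  cat(write_newick(x), "\n")
  invisible(x)
}
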