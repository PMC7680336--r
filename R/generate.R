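#' @title Seeded random rooted trees
#' @description
#' Topologies are sampled by random sequential leaf attachment (each new
#' leaf subdivides a uniformly chosen edge of the current tree), giving a
#' binary tree, followed by independent random contraction of
#' internal edges to create polytomies when `max_children > 2`.  The same
#' seed and configuration always reproduce the same tree; the RNG state of
#' the caller is left untouched.
#' @name random-trees
NULL

#' Generate a random rooted tree with unique rate labels
#'
#' @param leaf_count number of leaves (>= 2); taxa are named `t1..tn`
#' @param seed integer seed; identical seed and configuration give an
#'   identical tree
#' @param max_children maximum number of children per vertex (>= 2);
#'   2 gives binary trees, larger values allow polytomies created by random
#'   edge contraction
#' @param contract_prob probability of contracting each eligible internal
#'   edge when `max_children > 2`
#' @return a `phylosym_tree` with auto-generated unique rates
#' @examples
#' random_tree(5, seed = 7)
#' @export
random_tree <- function(leaf_count, seed, max_children = 2L,
                        contract_prob = 0.25) {
  if (leaf_count < 2L) stop("leaf_count must be at least 2", call. = FALSE)
  if (max_children < 2L) stop("max_children must be at least 2",
                              call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)

  ## grow a binary tree: vectors indexed by vertex id
  parent <- c(NA_integer_, 1L, 1L)
  children <- list(c(2L, 3L), integer(0), integer(0))
  leaves <- c(2L, 3L)
  for (k in seq_len(leaf_count - 2L)) {
    ## pick a vertex v != root; subdivide the edge above it
    nonroot <- setdiff(seq_along(parent), 1L)
    v <- nonroot[sample.int(length(nonroot), 1L)]
    p <- parent[v]
    mid <- length(parent) + 1L
    leaf <- length(parent) + 2L
    parent <- c(parent, p, mid)
    parent[v] <- mid
    children <- c(children, list(c(v, leaf)), list(integer(0)))
    children[[p]][children[[p]] == v] <- mid
    leaves <- c(leaves, leaf)
  }

  ## contract internal non-root edges at random to create polytomies
  if (max_children > 2L) {
    internal <- which(lengths(children) > 0L & !is.na(parent))
    for (v in internal[sample.int(length(internal))]) {
      p <- parent[v]
      if (stats::runif(1) < contract_prob &&
            length(children[[p]]) - 1L + length(children[[v]]) <=
              max_children) {
        at <- which(children[[p]] == v)
        children[[p]] <- append(children[[p]][-at], children[[v]],
                                after = at - 1L)
        for (w in children[[v]]) parent[w] <- p
        children[[v]] <- integer(0)
        parent[v] <- NA_integer_   # detached; compacted below
      }
    }
    keep <- !(is.na(parent) & seq_along(parent) != 1L)
    remap <- cumsum(keep)
    parent <- parent[keep]
    parent[!is.na(parent)] <- remap[parent[!is.na(parent)]]
    children <- lapply(children[keep], function(cs) remap[cs])
    leaves <- remap[leaves]
  }

  n <- length(parent)
  taxon <- rep(NA_character_, n)
  taxon[leaves] <- paste0("t", seq_along(leaves))
  rate <- rep(NA_character_, n)
  ord <- preorder_ids(parent, children, 1L)
  k <- 0L
  for (v in ord) {
    if (length(children[[v]]) > 0L) {
      k <- k + 1L
      rate[v] <- paste0("r", k)
    }
  }
  taxa_order <- taxon[ord[!is.na(taxon[ord])]]
  new_rooted_tree(parent, children, taxon, rate, taxa_order)
}
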