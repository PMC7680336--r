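#' @title Built-in example models
#' @description
#' Two small models ship with the package: `"fig1"`, a five-taxon tree with
#' four distinct rates whose basis is a convenient worked example, and
#' `"k2p"`, the four-state DNA tree `((A,G)b,(C,T)c)a;` which, once the two
#' cherry rates b and c are identified, generates the Kimura two-parameter
#' model: one rate for transitions (A<->G, C<->T) and one for
#' transversions.
#' @name fixtures
NULL

fixture_newick <- c(
  fig1 = "((1,2)beta,(3,(4,5)delta)gamma)alpha;",
  k2p = "((A,G)b,(C,T)c)a;"
)

#' Names of the built-in fixtures
#' @return character vector
#' @export
fixture_names <- function() names(fixture_newick)

#' Load a built-in fixture tree
#' @param name `"fig1"` or `"k2p"`
#' @return a `phylosym_tree`; for `"k2p"` the intended rate identification
#'   `{b, c}` is attached as `attr(tree, "rate_classes")`
#' @export
fixture_tree <- function(name = fixture_names()) {
  name <- match.arg(name)
  tr <- parse_newick(fixture_newick[[name]])
  if (name == "k2p") {
    attr(tr, "rate_classes") <- rate_classes(tr, list(c("b", "c")))
  }
  tr
}

## resolve a --tree argument: fixture name, file path, or literal Newick
resolve_tree <- function(spec, sort_taxa = FALSE) {
  if (spec %in% fixture_names()) {
    tr <- fixture_tree(spec)
    if (sort_taxa) {
      cls <- attr(tr, "rate_classes")
      tr <- parse_newick(write_newick(tr), sort_taxa = TRUE)
      attr(tr, "rate_classes") <- cls
    }
    return(tr)
  }
  text <- if (file.exists(spec)) {
    paste(readLines(spec, warn = FALSE), collapse = "")
  } else {
    spec
  }
  parse_newick(text, sort_taxa = sort_taxa, dup_rates = "merge")
}
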