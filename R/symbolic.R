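#' Symbolic pattern of the generic algebra element
#'
#' Renders the generic element of a (possibly constrained) model as an
#' n x n character matrix: off-diagonal cell (x, y) shows the equality-class
#' label of the rate at mrca(x, y); the diagonal is `"*"`, defined to give
#' zero row (and column) sum.
#' @param tree a `phylosym_tree`
#' @param classes a `phylosym_rate_classes` partition (default: all
#'   singletons)
#' @return a character matrix with taxon dimnames
#' @export
export_symbolic <- function(tree, classes = rate_classes(tree)) {
  stop_if_not_tree(tree)
  stop_if_not_classes(tree, classes)
  class_of <- stats::setNames(
    rep(names(classes), lengths(classes)), unlist(classes))
  tx <- taxa(tree)
  out <- matrix("*", length(tx), length(tx), dimnames = list(tx, tx))
  for (x in tx) {
    for (y in tx) {
      if (x != y) out[x, y] <- class_of[[tree$rate[mrca(tree, x, y)]]]
    }
  }
  out
}

#' Format a symbolic pattern for plain-text display
#' @param pattern output of [export_symbolic()]
#' @return character vector of lines
#' @export
format_symbolic <- function(pattern) {
  w <- max(nchar(c(pattern, colnames(pattern))))
  pad <- function(s) formatC(s, width = w)
  header <- paste(c(pad(""), pad(colnames(pattern))), collapse = " ")
  rows <- vapply(rownames(pattern), function(r) {
    paste(c(pad(r), pad(pattern[r, ])), collapse = " ")
  }, character(1))
  c(header, rows)
}
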