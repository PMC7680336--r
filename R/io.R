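#' @title Plain-text serialization
#' @description
#' Matrices travel as TSV with a taxon header row and a leading taxon
#' column, or as dense JSON `{taxa, rate, rows}`.  Graphs travel as
#' two-column TSV edge lists plus a JSON manifest recording each graph's
#' isolated vertices.
#' @name serialization
NULL

#' Write a matrix as taxon-headed TSV
#' @param m matrix with taxon dimnames
#' @param path file path, or `""` for stdout
#' @export
write_matrix_tsv <- function(m, path = "") {
  df <- data.frame(taxon = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a taxon-headed TSV matrix
#' @param path file path
#' @return matrix with taxon dimnames
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, colClasses = "character")
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- df[[1]]
  m
}

#' Dense JSON form of a basis matrix
#' @param m matrix with taxon dimnames
#' @param rate optional rate label recorded alongside
#' @return JSON string
#' @export
matrix_to_json <- function(m, rate = NULL) {
  jsonlite::toJSON(
    list(taxa = rownames(m), rate = rate,
         rows = unname(apply(m, 1, as.numeric, simplify = FALSE))),
    auto_unbox = TRUE, null = "null")
}

#' Write a TIGS as edge-list TSVs plus a JSON manifest
#'
#' One `<prefix><rate>.tsv` two-column edge list per graph, plus
#' `<prefix>manifest.json` listing, per graph, its rate, edge file and
#' isolated vertices.
#' @param g a `phylosym_tigs`
#' @param dir output directory (created if missing)
#' @param prefix file-name prefix
#' @return invisibly, the manifest path
#' @export
write_tigs <- function(g, dir, prefix = "graph_") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  entries <- list()
  for (i in seq_along(g$graphs)) {
    gr <- g$graphs[[i]]
    rate <- if (!is.null(gr$rate)) gr$rate else paste0("g", i)
    file <- file.path(dir, paste0(prefix, rate, ".tsv"))
    utils::write.table(gr$edges, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = c("from", "to"))
    entries[[length(entries) + 1L]] <- list(
      rate = rate, edges = basename(file),
      isolated = setdiff(gr$vertices, graph_support(gr)))
  }
  manifest <- file.path(dir, paste0(prefix, "manifest.json"))
  writeLines(jsonlite::toJSON(list(taxa = g$taxa, graphs = entries),
                              auto_unbox = TRUE), manifest)
  invisible(manifest)
}

#' Read a TIGS written by [write_tigs()]
#' @param manifest path to the JSON manifest
#' @return a `phylosym_tigs`
#' @export
read_tigs <- function(manifest) {
  spec <- jsonlite::fromJSON(manifest, simplifyVector = FALSE)
  tx <- unlist(spec$taxa)
  dir <- dirname(manifest)
  graphs <- lapply(spec$graphs, function(e) {
    df <- utils::read.table(file.path(dir, e$edges), sep = "\t",
                            header = TRUE, colClasses = "character")
    labeled_graph(tx, as.matrix(df), rate = e$rate)
  })
  tigs_set(graphs)
}
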