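#' Reading and writing networks and matrices
#'
#' Networks travel as TSV edge lists (`source<TAB>target[<TAB>label]`) or
#' GraphML; word-context matrices as Matrix Market (MTX) files with sidecar
#' row/column label files (one label per line).
#'
#' @name semnet-io
NULL

#' Write a network as a TSV edge list
#'
#' @param net an `igraph` graph
#' @param path output path; a `label` edge attribute, if present, becomes a
#'   third column
#' @export
write_edgelist <- function(net, path) {
  el <- igraph::as_edgelist(net)
  df <- data.frame(source = el[, 1], target = el[, 2])
  if ("label" %in% igraph::edge_attr_names(net))
    df$label <- igraph::E(net)$label
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a network from a TSV edge list
#'
#' @param path edge-list path (2 or 3 tab-separated columns, no header)
#' @param directed build a directed graph (default TRUE)
#' @return an `igraph` graph; a third column becomes the `label` edge
#'   attribute
#' @export
read_edgelist <- function(path, directed = TRUE) {
  if (!file.exists(path)) stopf("edge list not found: %s", path)
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stopf("edge list needs at least 2 columns")
  nodes <- unique(c(df[[1]], df[[2]]))
  g <- igraph::graph_from_data_frame(df[, 1:2], directed = directed,
                                     vertices = nodes)
  if (ncol(df) >= 3) igraph::E(g)$label <- df[[3]]
  g
}

#' Write a network as GraphML
#'
#' @inheritParams write_edgelist
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}

#' Write a word-context matrix as Matrix Market plus label sidecars
#'
#' Produces `<prefix>.mtx`, `<prefix>.rows` and `<prefix>.cols`.
#'
#' @param wcm a `word_context_matrix`
#' @param prefix path prefix for the three files
#' @export
write_wcm <- function(wcm, prefix) {
  stopifnot(inherits(wcm, "word_context_matrix"))
  Matrix::writeMM(wcm$M, paste0(prefix, ".mtx"))
  writeLines(rownames(wcm$M), paste0(prefix, ".rows"))
  writeLines(colnames(wcm$M), paste0(prefix, ".cols"))
  invisible(prefix)
}

#' Read a word-context matrix written by [write_wcm()]
#'
#' @param prefix path prefix
#' @param context_type,weighting metadata to attach (not stored in MTX)
#' @return a `word_context_matrix`
#' @export
read_wcm <- function(prefix, context_type = "document", weighting = "raw") {
  M <- Matrix::readMM(paste0(prefix, ".mtx"))
  M <- methods::as(M * 1, "CsparseMatrix") # pattern matrices -> numeric
  dimnames(M) <- list(readLines(paste0(prefix, ".rows")),
                      readLines(paste0(prefix, ".cols")))
  new_wcm(M, context_type, weighting)
}
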