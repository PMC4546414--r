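# Shared fixture builders. Everything is generated in code; no data files.

# write a temporary corpus file with the given lines, return its path
# (session tempdir; cleaned up by R on exit)
tmp_corpus_file <- function(lines) {
  path <- tempfile(fileext = ".txt")
  writeLines(lines, path)
  path
}

# a corpus object straight from token vectors
corpus_from_docs <- function(...) {
  path <- tempfile(fileext = ".txt")
  on.exit(unlink(path))
  writeLines(vapply(list(...), paste, character(1), collapse = " "), path)
  read_corpus(path)
}

# a semantic space whose first row "a" has the given cosines to the other
# rows; remaining geometry unconstrained (unit vectors)
space_with_cosines <- function(cosines) {
  labels <- c("a", names(cosines))
  V <- matrix(0, length(labels), 2 + length(cosines))
  V[1, 1] <- 1
  for (i in seq_along(cosines)) {
    V[i + 1, 1] <- cosines[[i]]
    V[i + 1, i + 1] <- sqrt(max(0, 1 - cosines[[i]]^2))
  }
  rownames(V) <- labels
  structure(list(vectors = V, provenance = "fixture"),
            class = "semantic_space")
}

# a random dense semantic space (reproducible)
random_space <- function(n_words, dim, seed) {
  set.seed(seed)
  V <- matrix(stats::rnorm(n_words * dim), n_words, dim)
  rownames(V) <- sprintf("w%02d", seq_len(n_words))
  structure(list(vectors = V, provenance = "fixture"),
            class = "semantic_space")
}

# directed graph from a two-column from/to character matrix
digraph <- function(from, to, nodes = NULL) {
  if (is.null(nodes)) nodes <- unique(c(from, to))
  g <- igraph::make_empty_graph(length(nodes), directed = TRUE)
  igraph::V(g)$name <- nodes
  igraph::add_edges(g, rbind(match(from, nodes), match(to, nodes)))
}

ungraph <- function(from, to, nodes = NULL) {
  igraph::as_undirected(digraph(from, to, nodes), mode = "collapse")
}

# windmill graph: eta triangles sharing a hub; hub degree 2*eta with local
# clustering 1/(2*eta - 1); every blade node has degree 2 and clustering 1
windmill <- function(eta, prefix = "v") {
  hub <- paste0(prefix, "hub")
  from <- to <- character(0)
  for (i in seq_len(eta)) {
    x <- sprintf("%s%db1", prefix, i)
    y <- sprintf("%s%db2", prefix, i)
    from <- c(from, hub, hub, x)
    to <- c(to, x, y, y)
  }
  ungraph(from, to)
}

# small taxonomy used across relclass tests:
#
#           root
#          /    \
#         A      B          C5 -> C4 -> C3 -> C2 -> C1_root (deep chain)
#        / \      \
#      A1   A2     B1
#     /  \           \
#   A1a  A1b          B1a
fixture_taxonomy <- function() {
  edges <- data.frame(
    child  = c("A", "B", "A1", "A2", "A1a", "A1b", "B1", "B1a",
               "C1", "C2", "C3", "C4", "C5", "D1", "D2", "D3", "D4", "D5"),
    parent = c("root", "root", "A", "A", "A1", "A1", "B", "B1",
               "deeproot", "C1", "C2", "C3", "C4",
               "deeproot", "D1", "D2", "D3", "D4"))
  map <- data.frame(
    word = c("x", "y", "g", "h", "deep_c", "deep_d", "b", "bb"),
    concept = c("A1", "A2", "A1a", "A", "C5", "D5", "B1", "B1a"))
  taxonomy(edges, map)
}
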