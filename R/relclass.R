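#' Paradigmatic vs syntagmatic edge classification
#'
#' Given a taxonomy (a DAG of is-a links between concepts plus a
#' word-to-concept map), an edge between two words is *paradigmatic* when any
#' concept pair across the two words (a) shares a direct parent, (b) is
#' linked by an is-a path of length at most 2 (super/subordination), or
#' (c) has a lowest common ancestor within `coord_depth` levels of both
#' (coordination; "closely positioned" is formalized this way since no exact
#' metric is standard -- it is an interpretation, not a replication of any
#' particular thesaurus traversal). Otherwise the edge is *syntagmatic*.
#' Words not mapped to any concept give label `unknown`, excluded from the
#' syntagmatic fraction q so that taxonomy coverage does not bias q.
#'
#' @name relclass
NULL

#' Construct a taxonomy
#'
#' @param edges data frame with columns `child`, `parent` (is-a links,
#'   child -> parent); must be acyclic
#' @param word_map data frame with columns `word`, `concept`; a word may map
#'   to several concepts
#' @return an object of class `taxonomy`
#' @export
taxonomy <- function(edges, word_map) {
  stopifnot(all(c("child", "parent") %in% names(edges)),
            all(c("word", "concept") %in% names(word_map)))
  concepts <- unique(c(edges$child, edges$parent, word_map$concept))
  g <- igraph::graph_from_data_frame(edges[, c("child", "parent")],
                                     directed = TRUE,
                                     vertices = data.frame(name = concepts))
  if (!igraph::is_dag(g)) stopf("taxonomy is cyclic")
  structure(list(graph = g,
                 word_map = data.frame(word = as.character(word_map$word),
                                       concept = as.character(word_map$concept),
                                       stringsAsFactors = FALSE)),
            class = "taxonomy")
}

#' Read a taxonomy from TSV files
#'
#' @param isa_path TSV with two columns, child and parent concept per line
#'   (no header)
#' @param map_path TSV with two columns, word and concept per line (no header)
#' @return a [taxonomy()]
#' @export
read_taxonomy <- function(isa_path, map_path) {
  isa <- read.delim(isa_path, header = FALSE, col.names = c("child", "parent"),
                    stringsAsFactors = FALSE)
  map <- read.delim(map_path, header = FALSE, col.names = c("word", "concept"),
                    stringsAsFactors = FALSE)
  taxonomy(isa, map)
}

# ancestors of a concept with their depths (self = 0), by upward BFS
ancestor_depths <- function(tax, concept) {
  d <- igraph::distances(tax$graph, v = concept, mode = "out")[1, ]
  d[is.finite(d)]
}

#' Classify a word pair as paradigmatic or syntagmatic
#'
#' @param tax a [taxonomy()]
#' @param w1,w2 words; the classification is symmetric in the two arguments
#' @param coord_depth depth bound for the coordination rule (default 2)
#' @return `"paradigmatic"`, `"syntagmatic"`, or `"unknown"` when either word
#'   is unmapped
#' @export
classify_edge <- function(tax, w1, w2, coord_depth = 2L) {
  stopifnot(inherits(tax, "taxonomy"))
  c1 <- tax$word_map$concept[tax$word_map$word == w1]
  c2 <- tax$word_map$concept[tax$word_map$word == w2]
  if (length(c1) == 0 || length(c2) == 0) return("unknown")
  for (a in c1) {
    da <- ancestor_depths(tax, a)
    for (b in c2) {
      if (a == b) return("paradigmatic") # shared concept (synonyms)
      db <- ancestor_depths(tax, b)
      # (a) shared direct parent
      if (length(intersect(names(da)[da == 1], names(db)[db == 1])) > 0)
        return("paradigmatic")
      # (b) is-a path of length <= 2 either way
      if ((b %in% names(da) && da[[b]] <= 2) ||
          (a %in% names(db) && db[[a]] <= 2))
        return("paradigmatic")
      # (c) lowest common ancestor within coord_depth of both
      common <- intersect(names(da), names(db))
      if (length(common) > 0 &&
          min(pmax(da[common], db[common])) <= coord_depth)
        return("paradigmatic")
    }
  }
  "syntagmatic"
}

#' Syntagmatic fraction q of a network's edges
#'
#' Classifies every edge (undirected sense) and returns the fraction of
#' labeled edges that are syntagmatic; `unknown` edges (unmapped words) are
#' excluded from q and counted separately.
#'
#' @param net an `igraph` graph over word labels
#' @param tax a [taxonomy()]
#' @param coord_depth passed to [classify_edge()]
#' @return list with `q`, per-edge `labels`, and `n_unknown`
#' @export
syntagmatic_fraction <- function(net, tax, coord_depth = 2L) {
  el <- igraph::as_edgelist(net)
  if (nrow(el) == 0) stopf("network has no edges")
  labels <- vapply(seq_len(nrow(el)), function(e)
    classify_edge(tax, el[e, 1], el[e, 2], coord_depth = coord_depth),
    character(1))
  n_syn <- sum(labels == "syntagmatic")
  n_par <- sum(labels == "paradigmatic")
  if (n_syn + n_par == 0) stopf("no edge could be labeled (taxonomy coverage 0)")
  list(q = n_syn / (n_syn + n_par), labels = labels,
       n_unknown = sum(labels == "unknown"))
}

#' Correlation between syntagmatic fraction and hierarchy strength
#'
#' Pearson correlation of the syntagmatic fractions q of a collection of
#' networks against their C(k)-k log-log correlation coefficients r (see
#' [hierarchy_fit()]). A positive correlation indicates that syntagmatic
#' edges weaken hierarchical structure.
#'
#' @param pairs data frame (or list coercible to one) with columns `q` and `r`
#' @return the Pearson correlation
#' @export
hierarchy_relation_correlation <- function(pairs) {
  pairs <- as.data.frame(pairs)
  stopifnot(all(c("q", "r") %in% names(pairs)))
  if (nrow(pairs) < 3) stopf("need at least 3 (q, r) pairs")
  if (stats::sd(pairs$q) == 0 || stats::sd(pairs$r) == 0)
    stopf("correlation undefined for constant input")
  cor(pairs$q, pairs$r)
}
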