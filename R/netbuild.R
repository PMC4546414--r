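#' Building directed semantic networks
#'
#' Networks are directed `igraph` graphs over word labels, built either from
#' association norms (cue -> associate edges filtered by participant count)
#' or from a semantic space by connecting each word to its nearest cosine
#' neighbors. Two neighborhood rules are provided: the k-nn rule, which fixes
#' each word's out-degree from an external degree sequence, and the
#' cumulative-similarity (cs) rule, which adds neighbors in descending cosine
#' order until their similarity mass exceeds a fraction R of the word's total
#' positive similarity mass.
#'
#' Negative cosines (possible after SVD) are excluded both from candidacy and
#' from the cs denominator: the cumulative ratio is ill-behaved with negative
#' mass. Exact cosine ties are broken toward the lexicographically smallest
#' label for reproducibility. Self-similarity is always excluded.
#'
#' @name netbuild
NULL

net_from_edges <- function(nodes, from, to, label = NULL) {
  g <- igraph::make_empty_graph(n = length(nodes), directed = TRUE)
  igraph::V(g)$name <- nodes
  if (length(from) > 0)
    g <- igraph::add_edges(g, rbind(match(from, nodes), match(to, nodes)))
  if (!is.null(label) && length(from) > 0) igraph::E(g)$label <- label
  g
}

#' Build a directed network from association norms
#'
#' Nodes are the cue words only (words appearing solely as associates are
#' dropped); a directed edge x -> y exists iff y is itself a cue and at least
#' `min_count` participants listed y as an associate of x.
#'
#' @param table an `association_table` (see [read_association_norms()]) or a
#'   data frame with columns `cue`, `associate`, `count`
#' @param min_count minimum participant count for an edge (default 2)
#' @return a directed `igraph` graph
#' @export
build_association_network <- function(table, min_count = 2L) {
  stopifnot(nrow(table) > 0)
  if (min_count < 1) stopf("min_count must be >= 1")
  cues <- unique(table$cue)
  keep <- table$count >= min_count & table$associate %in% cues &
    table$cue != table$associate
  net_from_edges(cues, table$cue[keep], table$associate[keep])
}

# descending-similarity candidate order for word i with lexicographic
# tie-break; returns candidate indices (negatives and self excluded)
ranked_candidates <- function(sims, labels, i) {
  s <- sims[i, ]
  s[i] <- -Inf
  cand <- which(s > 0)
  cand[order(-s[cand], labels[cand])]
}

#' k-nearest-neighbor network from a semantic space
#'
#' Each word gets directed edges to its top-k cosine neighbors, with k taken
#' from an externally supplied out-degree sequence (conventionally the
#' out-degree sequence of a reference association network, so the two
#' networks share their out-degree distribution exactly).
#'
#' @param space a `semantic_space` or `word_context_matrix`
#' @param out_degree_seq named integer vector: out-degree per word; every
#'   named word must exist in the space
#' @return a directed `igraph` graph whose out-degree sequence equals
#'   `out_degree_seq` exactly
#' @export
knn_network <- function(space, out_degree_seq) {
  V <- space_rows(space)
  labels <- rownames(V)
  stopifnot(!is.null(names(out_degree_seq)))
  if (!all(names(out_degree_seq) %in% labels))
    stopf("out-degree sequence names words absent from the space")
  if (any(out_degree_seq >= nrow(V)))
    stopf("out-degree >= vocabulary size")
  sims <- cosine_matrix(space)
  from <- to <- character(0)
  for (w in names(out_degree_seq)) {
    k <- out_degree_seq[[w]]
    if (k == 0) next
    i <- match(w, labels)
    s <- sims[i, ]
    s[i] <- -Inf
    nb <- order(-s, labels)[seq_len(k)]
    from <- c(from, rep(w, k))
    to <- c(to, labels[nb])
  }
  net_from_edges(labels, from, to)
}

#' Cumulative-similarity (cs) network from a semantic space
#'
#' For each word, neighbors are added in descending cosine order until the
#' ratio of their summed cosine to the summed positive cosine over all other
#' words strictly exceeds `R`. With `min_cosine` set, candidates at or below
#' the cutoff are excluded from the numerator and from edge creation, but the
#' denominator keeps all positive cosines, so R retains its meaning across
#' filtered and unfiltered runs. Words with no positive cosine get out-degree
#' 0 with a warning.
#'
#' @param space a `semantic_space` or `word_context_matrix`
#' @param R cumulative similarity threshold in (0, 1)
#' @param min_cosine optional lower cosine cutoff (the thresholded variant;
#'   0.05 is the conventional choice)
#' @return a directed `igraph` graph
#' @export
cs_network <- function(space, R, min_cosine = NULL) {
  stopifnot(R > 0, R < 1)
  V <- space_rows(space)
  labels <- rownames(V)
  sims <- cosine_matrix(space)
  from <- to <- character(0)
  starved <- 0L
  for (i in seq_along(labels)) {
    cand <- ranked_candidates(sims, labels, i)
    if (length(cand) == 0) {
      starved <- starved + 1L
      next
    }
    denom <- sum(sims[i, cand])
    if (!is.null(min_cosine))
      cand <- cand[sims[i, cand] > min_cosine]
    if (length(cand) == 0) next
    ratio <- cumsum(sims[i, cand]) / denom
    k <- match(TRUE, ratio > R)
    if (is.na(k)) k <- length(cand) # filtered mass can never exceed R
    nb <- cand[seq_len(k)]
    from <- c(from, rep(labels[i], k))
    to <- c(to, labels[nb])
  }
  if (starved > 0)
    warnf("%d word(s) had no positive cosine; out-degree 0", starved)
  net_from_edges(labels, from, to)
}

#' Tune the cs threshold R to a target mean out-degree
#'
#' Mean out-degree is monotone non-decreasing in R, so bisection applies.
#' Stops when the achieved mean out-degree is within `tolerance` of the
#' target or the R bracket is exhausted (the closest endpoint is returned).
#'
#' @inheritParams cs_network
#' @param target_mean_out_degree desired mean out-degree (>= 1, < n)
#' @param tolerance acceptable |mean out-degree - target| (default 0.1)
#' @param max_iter bisection iterations (default 40)
#' @return list with `R`, `mean_out_degree` and the `network` built at `R`
#' @export
tune_R <- function(space, target_mean_out_degree, tolerance = 0.1,
                   min_cosine = NULL, max_iter = 40L) {
  V <- space_rows(space)
  n <- nrow(V)
  stopifnot(target_mean_out_degree >= 1)
  if (target_mean_out_degree > n - 1)
    stopf("target mean out-degree exceeds n - 1 = %d", n - 1)
  lo <- 1e-9; hi <- 1 - 1e-9
  best <- NULL
  for (it in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    net <- suppressWarnings(cs_network(space, mid, min_cosine = min_cosine))
    k <- igraph::ecount(net) / n
    if (is.null(best) ||
        abs(k - target_mean_out_degree) < abs(best$k - target_mean_out_degree))
      best <- list(R = mid, k = k, net = net)
    if (abs(k - target_mean_out_degree) <= tolerance) break
    if (k < target_mean_out_degree) lo <- mid else hi <- mid
  }
  list(R = best$R, mean_out_degree = best$k, network = best$net)
}
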