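#' Network descriptors for semantic networks
#'
#' Descriptors follow the conventions of small-world and hierarchical-network
#' analysis: statistics of the largest (strongly) connected component, the
#' clustering coefficient as the mean of local coefficients on the undirected
#' projection, uniform random-graph baselines at matched size and density, and
#' the hierarchical scaling C(k) ~ k^-beta of the degree-averaged local
#' clustering coefficient.
#'
#' @name netstats
NULL

#' Undirected projection of a directed network
#'
#' Nodes x and y are joined by a single undirected edge iff x->y or y->x is
#' present; self-loops and multi-edges are collapsed.
#'
#' @param net an `igraph` graph
#' @return an undirected simple `igraph` graph
#' @export
undirected_projection <- function(net) {
  g <- igraph::as_undirected(net, mode = "collapse",
                             edge.attr.comb = "first")
  igraph::simplify(g, edge.attr.comb = "first")
}

#' Largest (strongly) connected component
#'
#' @param net an `igraph` graph
#' @param strong for directed input, use strong connectivity (the default);
#'   ignored for undirected input
#' @return the induced subgraph on the largest component (ties broken toward
#'   the first component index, deterministically)
#' @export
largest_component <- function(net, strong = TRUE) {
  stopifnot(igraph::vcount(net) > 0)
  mode <- if (igraph::is_directed(net) && strong) "strong" else "weak"
  comp <- igraph::components(net, mode = mode)
  igraph::induced_subgraph(net, which(comp$membership == which.max(comp$csize)))
}

#' Local clustering coefficients
#'
#' Computed on the undirected projection; nodes with degree < 2 get a local
#' coefficient of 0. The local coefficient is 2e / (k (k - 1)) with e the
#' number of edges among the node's neighbors.
#'
#' @param net an `igraph` graph (a directed graph is projected first)
#' @return named numeric vector of local coefficients, one per node
#' @export
local_clustering <- function(net) {
  und <- undirected_projection(net)
  lc <- igraph::transitivity(und, type = "local", isolates = "zero")
  lc[!is.finite(lc)] <- 0
  names(lc) <- igraph::V(und)$name
  lc
}

#' Clustering coefficient (mean of local coefficients)
#'
#' @inheritParams local_clustering
#' @return mean local clustering coefficient in `[0, 1]`
#' @export
clustering_coefficient <- function(net) mean(local_clustering(net))

#' Average shortest path length and diameter
#'
#' Distances are hop counts; directed distances respect edge direction and are
#' averaged over ordered reachable pairs, undirected over unordered pairs.
#' The input must be a single (strongly) connected component.
#'
#' @param net a connected `igraph` graph
#' @return list with `L` (mean shortest path length) and `D` (diameter)
#' @export
path_stats <- function(net) {
  mode <- if (igraph::is_directed(net)) "strong" else "weak"
  if (igraph::components(net, mode = mode)$no > 1)
    stopf("network is not a single %s component; apply largest_component() first",
          if (mode == "strong") "strongly connected" else "connected")
  list(L = igraph::mean_distance(net, directed = igraph::is_directed(net)),
       D = igraph::diameter(net, directed = igraph::is_directed(net)))
}

#' Random-graph baseline for small-world comparison
#'
#' Averages L and C over `reps` uniform simple random graphs with exactly `n`
#' nodes and `m` edges (G(n, m)); L is computed on the largest (strongly)
#' connected component of each replicate and C on the undirected projection.
#' A degree-preserving rewiring baseline is available behind
#' `degree_preserving = TRUE`, in which case `net` must be supplied.
#'
#' @param n,m node and edge counts of the reference network
#' @param directed generate directed random graphs
#' @param reps number of random graphs to average over (default 10)
#' @param seed optional RNG seed
#' @param degree_preserving rewire `net` keeping its degree sequence instead
#'   of drawing uniform G(n, m) graphs
#' @param net reference network; required when `degree_preserving = TRUE`
#' @return list with `L_random` and `C_random`
#' @export
random_baseline <- function(n, m, directed = FALSE, reps = 10L, seed = NULL,
                            degree_preserving = FALSE, net = NULL) {
  max_m <- if (directed) n * (n - 1) else n * (n - 1) / 2
  if (m > max_m) stopf("m = %d infeasible for a simple graph on %d nodes", m, n)
  if (degree_preserving && is.null(net))
    stopf("degree_preserving baseline needs the reference network")
  with_seed(seed, {
    L <- C <- numeric(reps)
    for (i in seq_len(reps)) {
      g <- if (degree_preserving)
        igraph::rewire(net, igraph::keeping_degseq(niter = 10 * m))
      else
        igraph::sample_gnm(n, m, directed = directed)
      L[i] <- igraph::mean_distance(largest_component(g),
                                    directed = igraph::is_directed(g))
      C[i] <- clustering_coefficient(g)
    }
    list(L_random = mean(L), C_random = mean(C))
  })
}

#' Hierarchical scaling of the local clustering coefficient
#'
#' Tests for hierarchical modularity via the scaling C(k) ~ k^-beta. `r` is
#' the Pearson correlation between log C(k) and log k over individual nodes
#' (nodes with k < 2 or C(k) = 0 are excluded -- their logarithm is
#' undefined); `beta` is the negative least-squares slope of log mean-C-at-k
#' against log k over distinct degrees.
#'
#' @param net an `igraph` graph; pass the component to analyze (conventionally
#'   the undirected projection of the largest strongly connected component)
#' @return list of class `hierarchy_stats` with `r`, `beta` and `points`
#'   (a data frame of degree and mean local clustering)
#' @export
hierarchy_fit <- function(net) {
  und <- undirected_projection(net)
  k <- igraph::degree(und)
  lc <- local_clustering(und)
  keep <- k >= 2 & lc > 0
  if (sum(keep) < 3) stopf("fewer than 3 usable (k, C(k)) points")
  # constant C(k) (or constant k) means no degree dependence: report r = 0
  r <- if (stats::sd(log(lc[keep])) == 0 || stats::sd(log(k[keep])) == 0) 0
       else cor(log(k[keep]), log(lc[keep]))
  agg <- aggregate(list(C = lc[k >= 2]), list(k = k[k >= 2]), mean)
  agg <- agg[agg$C > 0, ]
  if (nrow(agg) < 3) stopf("fewer than 3 distinct degrees with positive mean C(k)")
  beta <- -unname(coef(lm(log(C) ~ log(k), data = agg))[2])
  structure(list(r = r, beta = beta, points = agg), class = "hierarchy_stats")
}

#' @export
print.hierarchy_stats <- function(x, ...) {
  cat(sprintf("hierarchy_stats: r = %.3f, beta = %.3f (%d distinct degrees)\n",
              x$r, x$beta, nrow(x$points)))
  invisible(x)
}

#' Summary statistics of a semantic network
#'
#' Fills the standard descriptor table: node and edge counts, size of the
#' largest (strongly) connected component, mean degree (`m/n` directed,
#' `2m/n` undirected), maximum degree (maximum in-degree for directed input),
#' diameter and mean shortest path length on the largest component, mean local
#' clustering coefficient on the undirected projection, and uniform random
#' baselines at matched n and m.
#'
#' @param net an `igraph` graph
#' @param reps random-baseline replicates (default 10); 0 skips the baseline
#' @param seed optional RNG seed for the baseline
#' @return list of class `network_stats`
#' @export
network_summary <- function(net, reps = 10L, seed = NULL) {
  directed <- igraph::is_directed(net)
  n <- igraph::vcount(net)
  m <- igraph::ecount(net)
  comp <- largest_component(net)
  ps <- path_stats(comp)
  base <- if (reps > 0)
    random_baseline(n, m, directed = directed, reps = reps, seed = seed)
  else list(L_random = NA_real_, C_random = NA_real_)
  structure(list(
    n = n, m = m, n_CC = igraph::vcount(comp),
    mean_degree = if (directed) m / n else 2 * m / n,
    k_max = max(igraph::degree(net, mode = if (directed) "in" else "all")),
    D = ps$D, L = ps$L, C = clustering_coefficient(net),
    L_random = base$L_random, C_random = base$C_random),
    class = "network_stats")
}

#' @export
print.network_stats <- function(x, ...) {
  cat(sprintf(
    "network_stats: n = %d, m = %d, n_CC = %d, <k> = %.2f, k_max = %d\n",
    x$n, x$m, x$n_CC, x$mean_degree, x$k_max))
  cat(sprintf("  D = %d, L = %.3f, C = %.4f (random: L = %.3f, C = %.4f)\n",
              x$D, x$L, x$C, x$L_random, x$C_random))
  invisible(x)
}
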