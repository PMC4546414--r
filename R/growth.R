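#' Growing-network models of semantic development
#'
#' The central simulator grows a directed network by mixing two attachment
#' mechanisms: *semantic differentiation* (a host node is chosen with
#' probability proportional to its total degree and the new node connects to
#' the host itself plus randomly chosen differentiation-labeled neighbors of
#' the host -- a variant of preferential attachment) and *experiential
#' correlation* (the new node connects to uniformly chosen existing nodes --
#' random attachment). Each of
#' the M edges a new node contributes is labeled "correlation" with
#' probability `p` and "differentiation" otherwise, and points toward the
#' existing node with probability `gamma`. With `p = 0` the model reduces to
#' pure semantic differentiation.
#'
#' @name growth
NULL

#' Configuration for the growth simulator
#'
#' @param n final number of nodes
#' @param M edges contributed by each new node (also the seed-clique size)
#' @param p probability an edge is added by random attachment (experiential
#'   correlation) rather than preferential attachment (semantic
#'   differentiation)
#' @param gamma probability an edge points toward the existing node
#' @param utility neighbor-choice utility within the host's neighborhood;
#'   only `"equal"` (uniform choice) is implemented -- the log-frequency
#'   utility would require an external word-frequency table
#' @param seed optional RNG seed
#' @return a list of class `growth_config`
#' @export
growth_config <- function(n, M = 13L, p = 0, gamma = 0.95,
                          utility = c("equal", "log_frequency"), seed = NULL) {
  utility <- match.arg(utility)
  if (utility == "log_frequency")
    stopf("log_frequency utility requires a frequency table; not implemented")
  stopifnot(n > M, M >= 1, p >= 0, p <= 1, gamma >= 0, gamma <= 1)
  structure(list(n = as.integer(n), M = as.integer(M), p = p, gamma = gamma,
                 utility = utility, seed = seed),
            class = "growth_config")
}

#' Grow a directed semantic network by mixed preferential/random attachment
#'
#' Starts from a fully connected directed seed of `M` nodes (`M(M-1)` directed
#' edges, labeled "differentiation") and adds `n - M` nodes, each contributing
#' exactly `M` distinct edges, so the directed edge count is always
#' `(n - M) M + M (M - 1)`. See [growth_config()] for the parameters.
#'
#' @param config a [growth_config()]
#' @return a directed `igraph` graph with an edge attribute `label`
#'   ("differentiation" or "correlation") and a graph attribute `hosts`
#'   recording the differentiation host chosen at each growth step (`NA` when
#'   a step had no differentiation edges)
#' @export
grow_network <- function(config) {
  stopifnot(inherits(config, "growth_config"))
  res <- with_seed(config$seed,
    .grow_st_cpp(config$n, config$M, config$p, config$gamma))
  g <- igraph::make_empty_graph(n = config$n, directed = TRUE)
  g <- igraph::add_edges(g, rbind(res$from, res$to))
  igraph::E(g)$label <-
    c("differentiation", "correlation")[res$label + 1L]
  igraph::V(g)$name <- paste0("v", seq_len(config$n))
  g <- igraph::set_graph_attr(g, "hosts", res$hosts)
  g <- igraph::set_graph_attr(g, "growth_config",
                              config[c("n", "M", "p", "gamma")])
  g
}

#' Tune gamma so the largest strongly connected component matches a target
#'
#' Scans `gamma = 1, 1 - step, 1 - 2 step, ...`, generating `reps` networks at
#' each value and averaging the size of the largest strongly connected
#' component (n_CC). Mean n_CC grows as gamma decreases; the scan stops once
#' the running mean passes `target_ncc` and returns the scanned gamma whose
#' mean n_CC is closest to the target, together with the single replicate at
#' that gamma whose own n_CC is closest to the target.
#'
#' @param config a [growth_config()]; its `gamma` field is ignored
#' @param target_ncc target size of the largest strongly connected component
#' @param step scan step for gamma (default 0.005)
#' @param reps replicates per gamma value (default 50)
#' @return list of class `tune_result` with `gamma`, `mean_ncc_by_gamma`,
#'   `network` (the chosen replicate as an igraph graph), `ncc` (its n_CC)
#'   and `reps`
#' @export
tune_gamma <- function(config, target_ncc, step = 0.005, reps = 50L) {
  stopifnot(inherits(config, "growth_config"), step > 0, reps >= 1,
            target_ncc <= config$n)
  with_seed(config$seed, {
    gammas <- seq(1, 0, by = -step)
    means <- numeric(0)
    prev <- NULL # per-gamma record: list(gamma, mean, edges, nccs)
    best <- NULL
    for (g in gammas) {
      runs <- vector("list", reps)
      nccs <- numeric(reps)
      for (r in seq_len(reps)) {
        sim <- .grow_st_cpp(config$n, config$M, config$p, g)
        nccs[r] <- .ncc_strong_cpp(sim$from, sim$to, config$n)
        runs[[r]] <- sim
      }
      cur <- list(gamma = g, mean = mean(nccs), runs = runs, nccs = nccs)
      means <- c(means, cur$mean)
      names(means)[length(means)] <- format(g)
      if (cur$mean >= target_ncc) {
        best <- if (!is.null(prev) &&
                    abs(prev$mean - target_ncc) < abs(cur$mean - target_ncc))
          prev else cur
        break
      }
      prev <- cur
    }
    if (is.null(best))
      stopf("target n_CC = %d unreachable: mean n_CC at gamma = 0 is %.1f",
            target_ncc, means[length(means)])
    i <- which.min(abs(best$nccs - target_ncc))
    sim <- best$runs[[i]]
    g <- igraph::make_empty_graph(n = config$n, directed = TRUE)
    g <- igraph::add_edges(g, rbind(sim$from, sim$to))
    igraph::E(g)$label <- c("differentiation", "correlation")[sim$label + 1L]
    igraph::V(g)$name <- paste0("v", seq_len(config$n))
    structure(list(gamma = best$gamma, mean_ncc_by_gamma = means,
                   network = g, ncc = best$nccs[i], reps = reps),
              class = "tune_result")
  })
}

#' @export
print.tune_result <- function(x, ...) {
  cat(sprintf("tune_result: gamma = %g (chosen replicate n_CC = %d; %d reps/step)\n",
              x$gamma, x$ncc, x$reps))
  invisible(x)
}

#' Barabasi-Albert preferential-attachment baseline
#'
#' Undirected growth from a complete seed of `M` nodes; each new node attaches
#' to `M` distinct existing nodes chosen with probability proportional to
#' their degrees. The degree distribution approaches P(k) ~ k^-3 in the tail.
#'
#' @param n final node count
#' @param M edges per new node
#' @param seed optional RNG seed
#' @return an undirected `igraph` graph
#' @export
ba_network <- function(n, M, seed = NULL) {
  stopifnot(n > M, M >= 1)
  res <- with_seed(seed, .grow_mixed_cpp(n, M, 0))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::add_edges(g, rbind(res$from, res$to))
}

#' Mixed preferential/random attachment baseline
#'
#' As [ba_network()], but each attachment is uniform over existing nodes with
#' probability `p` and degree-proportional otherwise. The degree distribution
#' follows a pure power law at `p = 0` and an exponential at `p = 1`; in
#' between it decays exponentially for small k with power-law-like tails.
#'
#' @inheritParams ba_network
#' @param p probability of uniform (random) attachment per edge
#' @return an undirected `igraph` graph
#' @export
liu_network <- function(n, M, p, seed = NULL) {
  stopifnot(n > M, M >= 1, p >= 0, p <= 1)
  res <- with_seed(seed, .grow_mixed_cpp(n, M, p))
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  igraph::add_edges(g, rbind(res$from, res$to))
}

#' Map a model preset name to the random-attachment probability p
#'
#' Model A sets `p = q` (all syntagmatic edges arise from random attachment),
#' Model B sets `p = q/2` (half of them do) and Model ST sets `p = 0` (pure
#' semantic differentiation), where `q` is the syntagmatic fraction of edges
#' in the target network (see [syntagmatic_fraction()]).
#'
#' @param name `"A"`, `"B"` or `"ST"`
#' @param q syntagmatic edge fraction in `[0, 1]`
#' @return the probability `p`
#' @export
model_preset <- function(name = c("A", "B", "ST"), q) {
  name <- match.arg(name)
  stopifnot(q >= 0, q <= 1)
  switch(name, A = q, B = q / 2, ST = 0)
}
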