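#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Growing-network simulators. All randomness goes through R's RNG (unif_rand)
// so set.seed() on the R side makes every run reproducible.

namespace {

// uniform integer in [0, n)
inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k; // guard against unif_rand() == 1.0
}

// draw `want` distinct unmarked values uniformly from [0, t) by rejection;
// marks and appends them to `chosen`
inline void draw_uniform_distinct(int t, int want, std::vector<char> &mark,
                                  std::vector<int> &chosen) {
  int got = 0;
  while (got < want) {
    int u = runif_int(t);
    if (!mark[u]) {
      mark[u] = 1;
      chosen.push_back(u);
      ++got;
    }
  }
}

} // namespace

// Modified Steyvers-Tenenbaum growth model.
//
// Seed: a fully connected directed clique of M nodes (M(M-1) directed edges,
// all labeled "differentiation", coded 0). Each later node contributes exactly
// M distinct edges: edges are labeled "correlation" (coded 1) with probability
// p, else "differentiation". The M_p differentiation edges connect the new
// node to a host chosen with probability proportional to its total degree and
// to M_p - 1 nodes drawn uniformly from the host's differentiation-labeled
// neighbors; shortfalls fall back first to the host's remaining neighbors,
// then to uniform draws over all existing nodes. Correlation endpoints are
// uniform over all existing nodes. Each edge points toward the existing node
// with probability gamma.
//
// Returns 1-based endpoints, per-edge labels, and the host chosen at each
// growth step (-1 when the step had no differentiation edges).
// [[Rcpp::export(name = ".grow_st_cpp")]]
List grow_st_cpp(int n, int M, double p, double gamma) {
  if (M < 1 || n <= M)
    stop("need n > M >= 1");
  const int m = (n - M) * M + M * (M - 1);
  IntegerVector from(m), to(m), label(m);
  IntegerVector hosts(n - M);

  // adjacency (undirected sense) with the label of the connecting edge
  std::vector<std::vector<int> > nbr(n), nlab(n);
  // one entry per directed-edge endpoint => sampling the bag is
  // degree-proportional in total (in + out) degree
  std::vector<int> bag;
  bag.reserve(2 * (size_t)m);
  std::vector<char> mark(n, 0);
  std::vector<int> chosen, clab, cand;
  chosen.reserve(M);
  clab.reserve(M);

  int e = 0;
  for (int i = 0; i < M; ++i) {
    for (int j = 0; j < M; ++j) {
      if (i == j) continue;
      from[e] = i + 1; to[e] = j + 1; label[e] = 0; ++e;
      bag.push_back(i); bag.push_back(j);
    }
  }
  for (int i = 0; i < M; ++i)
    for (int j = 0; j < M; ++j)
      if (i != j) { nbr[i].push_back(j); nlab[i].push_back(0); }

  for (int t = M; t < n; ++t) {
    int Mp = 0;
    for (int k = 0; k < M; ++k)
      if (unif_rand() >= p) ++Mp; // differentiation with prob 1 - p
    const int Mr = M - Mp;
    chosen.clear(); clab.clear();
    int host = -1;

    if (Mp > 0) {
      host = bag[runif_int((int)bag.size())];
      // the new node links to the differentiated host itself ...
      mark[host] = 1;
      chosen.push_back(host);
      clab.push_back(0);
      const int Mp_nb = Mp - 1; // ... plus Mp - 1 of its neighbors
      // differentiation-labeled neighbors of the host
      cand.clear();
      const std::vector<int> &hn = nbr[host];
      const std::vector<int> &hl = nlab[host];
      for (size_t i = 0; i < hn.size(); ++i)
        if (hl[i] == 0 && !mark[hn[i]]) cand.push_back(hn[i]);
      int take = (int)cand.size() < Mp_nb ? (int)cand.size() : Mp_nb;
      // partial Fisher-Yates draw of `take` distinct candidates
      for (int i = 0; i < take; ++i) {
        int j = i + runif_int((int)cand.size() - i);
        std::swap(cand[i], cand[j]);
        mark[cand[i]] = 1;
        chosen.push_back(cand[i]);
        clab.push_back(0);
      }
      int short1 = Mp_nb - take;
      if (short1 > 0) {
        // fallback 1: remaining neighbors of the host, any label
        cand.clear();
        for (size_t i = 0; i < hn.size(); ++i)
          if (!mark[hn[i]]) cand.push_back(hn[i]);
        int take2 = (int)cand.size() < short1 ? (int)cand.size() : short1;
        for (int i = 0; i < take2; ++i) {
          int j = i + runif_int((int)cand.size() - i);
          std::swap(cand[i], cand[j]);
          mark[cand[i]] = 1;
          chosen.push_back(cand[i]);
          clab.push_back(0);
        }
        int short2 = short1 - take2;
        if (short2 > 0) {
          // fallback 2: uniform over all existing nodes
          size_t before = chosen.size();
          draw_uniform_distinct(t, short2, mark, chosen);
          for (size_t i = before; i < chosen.size(); ++i) clab.push_back(0);
        }
      }
    }
    if (Mr > 0) {
      size_t before = chosen.size();
      draw_uniform_distinct(t, Mr, mark, chosen);
      for (size_t i = before; i < chosen.size(); ++i) clab.push_back(1);
    }

    for (size_t i = 0; i < chosen.size(); ++i) {
      const int u = chosen[i];
      const int l = clab[i];
      if (unif_rand() < gamma) { from[e] = t + 1; to[e] = u + 1; }
      else                     { from[e] = u + 1; to[e] = t + 1; }
      label[e] = l; ++e;
      nbr[t].push_back(u); nlab[t].push_back(l);
      nbr[u].push_back(t); nlab[u].push_back(l);
      bag.push_back(u); bag.push_back(t);
      mark[u] = 0;
    }
    hosts[t - M] = host < 0 ? NA_INTEGER : host + 1;
  }

  return List::create(_["from"] = from, _["to"] = to, _["label"] = label,
                      _["hosts"] = hosts);
}

// Barabasi-Albert / Liu-style mixed-attachment baseline (undirected).
// Seed: complete graph on M nodes. Each new node attaches to M distinct
// existing nodes; each attachment is uniform over existing nodes with
// probability p, else degree-proportional (p = 0 gives plain BA).
// [[Rcpp::export(name = ".grow_mixed_cpp")]]
List grow_mixed_cpp(int n, int M, double p) {
  if (M < 1 || n <= M)
    stop("need n > M >= 1");
  const int m = M * (M - 1) / 2 + (n - M) * M;
  IntegerVector from(m), to(m);
  std::vector<int> bag;
  bag.reserve(2 * (size_t)m);
  std::vector<char> mark(n, 0);
  std::vector<int> chosen;
  chosen.reserve(M);

  int e = 0;
  for (int i = 0; i < M; ++i) {
    for (int j = i + 1; j < M; ++j) {
      from[e] = i + 1; to[e] = j + 1; ++e;
      bag.push_back(i); bag.push_back(j);
    }
  }
  for (int t = M; t < n; ++t) {
    chosen.clear();
    while ((int)chosen.size() < M) {
      int u;
      if (unif_rand() < p) u = runif_int(t);
      else                 u = bag[runif_int((int)bag.size())];
      if (!mark[u]) { mark[u] = 1; chosen.push_back(u); }
    }
    for (size_t i = 0; i < chosen.size(); ++i) {
      const int u = chosen[i];
      from[e] = t + 1; to[e] = u + 1; ++e;
      bag.push_back(u); bag.push_back(t);
      mark[u] = 0;
    }
  }
  return List::create(_["from"] = from, _["to"] = to);
}

// Size of the largest strongly connected component (iterative Tarjan).
// Used by the gamma-tuning loop, where building an igraph object per
// replicate would dominate the runtime.
// [[Rcpp::export(name = ".ncc_strong_cpp")]]
int ncc_strong_cpp(IntegerVector from, IntegerVector to, int n) {
  const int m = from.size();
  std::vector<int> head(n, -1), nxt(m), dst(m);
  for (int e = 0; e < m; ++e) {
    int u = from[e] - 1;
    dst[e] = to[e] - 1;
    nxt[e] = head[u];
    head[u] = e;
  }
  std::vector<int> index(n, -1), low(n, 0), comp(n, -1);
  std::vector<char> onstk(n, 0);
  std::vector<int> stk, callv, calle;
  stk.reserve(n); callv.reserve(n); calle.reserve(n);
  int idx = 0, best = 0;

  for (int s = 0; s < n; ++s) {
    if (index[s] != -1) continue;
    callv.clear(); calle.clear();
    callv.push_back(s); calle.push_back(head[s]);
    index[s] = low[s] = idx++;
    stk.push_back(s); onstk[s] = 1;
    while (!callv.empty()) {
      int v = callv.back();
      int &e = calle.back();
      if (e != -1) {
        int w = dst[e];
        e = nxt[e];
        if (index[w] == -1) {
          index[w] = low[w] = idx++;
          stk.push_back(w); onstk[w] = 1;
          callv.push_back(w); calle.push_back(head[w]);
        } else if (onstk[w] && index[w] < low[v]) {
          low[v] = index[w];
        }
      } else {
        callv.pop_back(); calle.pop_back();
        if (!callv.empty() && low[v] < low[callv.back()])
          low[callv.back()] = low[v];
        if (low[v] == index[v]) {
          int sz = 0;
          while (true) {
            int w = stk.back(); stk.pop_back();
            onstk[w] = 0; ++sz;
            if (w == v) break;
          }
          if (sz > best) best = sz;
        }
      }
    }
  }
  return best;
}
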