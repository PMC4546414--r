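---
title: "Semantic networks from distributional models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Semantic networks from distributional models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Free word association produces directed lexical networks with three robust
structural signatures: they are *small-world* (clustering far above a random
graph of the same density, path lengths comparable to it), their in-degree
distributions follow a *truncated power law* `P(k) ~ k^-alpha exp(-lambda k)`
rather than a pure power law, and they are *hierarchically modular* — the
local clustering coefficient of a node falls with its degree roughly as
`C(k) ~ k^-beta`. Whether distributional semantic models (DSMs) — word
vectors built from corpus co-occurrence statistics — give rise to networks
with the same signatures is a direct test of their adequacy as models of
human semantic memory. `semnetkit` implements the full measurement pipeline
(matrix construction, weighting, smoothing, network construction, network
statistics, a rigorous degree-distribution protocol) together with a
growing-network model that explains how these signatures can emerge from two
complementary attachment mechanisms.

## Pipeline

### Word-context matrices

`build_matrix()` produces a sparse count matrix with target words as rows.
Contexts are either whole documents (`f_ij` = occurrences of word i in
document j) or co-occurring words within a symmetric window (default
half-width 2, the conventional choice for word-word matrices). Windows never
cross document boundaries; a token does not co-occur with itself at its own
position, but two positions of the same type within a window count, in both
directions, so the full-vocabulary word-word matrix is symmetric.

### Weighting

`weight_matrix()` offers two schemes, both applied to raw counts only:

* **tf-idf (log-entropy)**: `a_ij = log(f_ij + 1) * g_i` with the global
  entropy weight `g_i = 1 + sum_k P_ik log(P_ik) / log(n_c)` and
  `P_ij = f_ij / sum_k f_ik`. A word distributed uniformly over all contexts
  carries no information and its row collapses to zero.
* **ppmi**: pointwise mutual information with negative values clamped to
  zero; zero counts stay zero (no smoothing constants), so ppmi never makes
  the stored matrix denser.

Natural logarithms are used throughout. The entropy term divides by
`log(n_c)`, so the base cancels there; elsewhere a change of base rescales
rows uniformly and leaves every cosine unchanged.

### Smoothing

`smooth_svd()` maps a matrix to a dense semantic space via truncated SVD.
Word vectors are the rows of `U_r %*% diag(d_r)` (the classical LSA
convention), so pairwise cosines equal those of the rank-`n_r`
reconstruction. The conventional dimensionality at full corpus scale is
`n_r = 300`; the implementation uses a dense decomposition, which is exact
and entirely adequate at the scales the package targets (up to a few
thousand rows) but not tuned for very large vocabularies.

### Network construction

Two neighborhood rules turn a semantic space into a directed network:

* **k-nn**: each word's out-degree is imposed from an external degree
  sequence (typically the out-degrees of a reference association network, so
  both networks share that distribution exactly).
* **cs (cumulative similarity)**: neighbors are added in descending cosine
  order until their summed cosine strictly exceeds a fraction `R` of the
  word's total positive cosine mass. `tune_R()` bisects `R` to match a
  target mean out-degree (mean out-degree is monotone in `R`). A
  `min_cosine` cutoff (conventionally 0.05) excludes near-noise candidates
  from the numerator and from edge creation while leaving the denominator
  unchanged, so `R` keeps its meaning across filtered and unfiltered runs.

Numerical conventions, chosen once for reproducibility: negative cosines
(possible after SVD) are excluded from candidacy and from the denominator —
a cumulative *ratio* is ill-behaved with negative mass; exact cosine ties
are broken toward the lexicographically smallest label; self-similarity is
always excluded. An undirected thresholding rule (connect every pair above a
fixed cosine) is deliberately not provided: word association is
asymmetric, and a symmetric rule cannot represent that.

`build_association_network()` builds the reference network from norms data:
nodes are cue words only, and x→y requires that at least `min_count`
participants (default 2) listed y as an associate of x.

### Network statistics

`network_summary()` reports n, m, the size of the largest (strongly)
connected component, mean degree, maximum in-degree, diameter and mean
shortest path length on the largest component, the clustering coefficient,
and random baselines. Conventions that matter:

* **Clustering** is the mean of local coefficients `2e/(k(k-1))` computed on
  the *undirected projection* (degree < 2 contributes 0). The mean-of-local
  convention (not the triangle/transitivity ratio) is what the `C(k)`
  analysis averages, so the two are consistent.
* **Random baseline** (`random_baseline()`) is the uniform simple random
  graph with the same n and m, averaged over 10 replicates by default: its
  expected clustering is the edge density, which is the comparison the
  small-world criterion `C >> C_random` intends. A degree-preserving
  rewiring baseline is available behind a flag, but with heavy-tailed degree
  sequences it retains substantial clustering and is not the default.
* **Hierarchy** (`hierarchy_fit()`): `r` is the Pearson correlation of
  `log C(k)` against `log k` over nodes (nodes with `k < 2` or `C(k) = 0`
  are excluded — their logarithm is undefined; this exclusion is forced by
  the log scale and documented rather than optional). `beta` is the negative
  least-squares slope through `(log k, log mean-C-at-k)` over distinct
  degrees. If `C(k)` is exactly constant, `r` is reported as 0 (no degree
  dependence) rather than `NA`.

### Degree-distribution protocol

In-degree samples (zeros excluded, their count recorded) are fitted by
*discrete* maximum likelihood — degrees are integers, and continuous
approximations distort the head of the distribution. Three families are
supported on integer supports `[k_min, k_max]`:

* power law `P(k) ~ k^-alpha`, normalized by the Hurwitz zeta function
  (Euler–Maclaurin evaluation, accurate to ~1e-12);
* truncated power law `P(k) ~ k^-alpha exp(-lambda k)`, normalized by
  direct summation with a length that scales as `1/lambda`, plus a
  midpoint-rule integral for the remaining tail (relative error below 1e-10);
* exponential `P(k) ~ exp(-lambda k)` (geometric), with a closed-form
  normalizer.

The fitting protocol follows the standard statistical treatment of
power-law data:

1. `scan_kmin()` selects the lower bound by minimizing the
   Kolmogorov–Smirnov distance between empirical and fitted CDFs, scanning
   `k_min <= 50` by default (capping the scan avoids discarding most of the
   data when the KS distance keeps decreasing).
2. `gof_bootstrap()` computes a semi-parametric goodness-of-fit p-value:
   synthetic samples mix resampled below-`k_min` data with draws from the
   fitted tail, each re-fitted with its own `k_min` scan; the power law is
   plausible when `p > 0.1`. The default 1,000 bootstrap sets give a p
   resolution of 0.001, ample for that decision rule.
3. `cv_select()` compares the three families by 10-fold cross-validated
   held-out log-likelihood on the tail, with a common `k_min` for all
   three (folds are drawn from the tail only). The truncated family nests
   the power law at `lambda = 0`, so on pure power-law data the two are
   statistically indistinguishable and either selection counts as correct.
4. `fit_below_kmin()` applies the same machinery to the head of the
   distribution on the finite support `[1, k_min - 1]` — association
   networks typically decay exponentially below `k_min`.

`sample_family()` draws exact inverse-CDF samples from any of the fitted
families and is the engine of both the bootstrap and the recovery tests.
All optimizations run to relative tolerance 1e-6 or better; unit tests pin
the MLEs to dense grid-search oracles within one grid step.

### Growth model

`grow_network()` grows a directed network from a fully connected directed
seed clique of `M` nodes. Each new node contributes exactly `M` distinct
edges, so the edge count is always `(n - M) M + M (M - 1)`. Each edge is
labeled **experiential correlation** with probability `p` (its endpoint is a
uniformly random existing node — random attachment) or **semantic
differentiation** otherwise. The differentiation edges attach the new node
to a *host* — an existing node drawn with probability proportional to its
total degree — and to `M_p - 1` nodes drawn uniformly from the host's
differentiation-labeled neighbors. Each edge points toward the existing
node with probability `gamma`, which controls how strongly connected the
resulting directed network is: `gamma = 1` makes every post-seed edge leave
its new node, so the strongly connected component stays frozen at the seed,
and the component grows as `gamma` decreases. `tune_gamma()` reproduces the
standard calibration: scan `gamma` downward from 1 in steps of 0.005, 50
replicates per value, stop once the mean component size passes the target,
and analyze the single replicate whose component size is closest to it.

Design choices in this module were genuinely open and are worth recording:

* **Differentiation wiring.** The textbook description of semantic
  differentiation connects a new word only to neighbors of the
  differentiated word. We connect the new word to the differentiated word
  *itself* plus `M_p - 1` of its neighbors. Conceptually, a word that
  differentiates an existing concept (a *cherry pie* is a kind of *pie*)
  acquires a relation to that concept, not only to its neighborhood.
  Structurally, the choice is decisive: at n = 5,018 and M = 13 the
  host-inclusive wiring yields strongly clustered, hierarchically organized
  networks (C around 0.26, C(k)–k correlation around -0.71 — the regime the
  model is meant to produce), whereas the neighbors-only variant collapses
  to C around 0.02 with almost no degree dependence of C(k). The package's
  tests and acceptance report are computed under the host-inclusive wiring.
* **Host degree** is total (in + out) degree; direction plays no role in
  how attractive a node is as a differentiation target.
* **Fallbacks** preserve the M-edge budget exactly: if the host has fewer
  than `M_p - 1` unchosen differentiation-labeled neighbors, the shortfall
  is drawn first from its remaining neighbors, then uniformly from all
  existing nodes, never creating duplicates.
* **Neighbor utility** is the equal-utility rule (uniform choice within the
  host's neighborhood). A log-frequency utility would need an external
  word-frequency table and an ordering assumption for word entry, neither
  of which has a principled default, so it is not implemented.
* **Seed labeling**: seed-clique edges count as differentiation edges, so
  early hosts have usable neighborhoods at any `p`.

`ba_network()` (pure preferential attachment) and `liu_network()` (per-edge
mixture of preferential and uniform attachment) provide the two classical
baselines: the former's degree tail approaches `k^-3`, the latter
interpolates from a pure power law at `p = 0` to a pure exponential at
`p = 1`, with an exponential head and power-like tail in between.
`model_preset()` maps a measured syntagmatic edge fraction `q` to the three
conventional parameter settings: `p = q` (Model A, all syntagmatic relations
from random attachment), `p = q/2` (Model B, half of them), `p = 0`
(Model ST, pure differentiation).

One numerical fact deserves a note because it is easy to misread: the
asymptotic tail exponent of the preferential-attachment degree distribution
is 3, but the exact pmf behaves like `1/(k(k+1)(k+2))`, whose local
log-log slope at `k = M = 5` is only about 2.55. A discrete MLE anchored at
`k_min = M` therefore lands near **2.77**, not 3.0 — both a closed-form
computation against the exact pmf and independent simulation agree. The
package reports the honestly estimated value; recovering an estimate close
to 3 requires fitting much deeper in the tail.

### Relation classification

`classify_edge()` labels a word pair *paradigmatic* when any concept pair
across the two words (a) shares a direct parent in the supplied is-a
taxonomy, (b) is linked by an is-a path of length at most 2, or (c) has a
lowest common ancestor within `coord_depth` levels of both. "Closely
positioned in the hierarchy" has no standard quantitative definition;
rule (c) with a configurable depth (default 2) is our interpretation, not a
replication of any particular thesaurus traversal, and the default is
deliberately conservative. Unmapped words yield `unknown`, which
`syntagmatic_fraction()` excludes from the fraction `q` so that taxonomy
coverage does not bias it. Increasing `coord_depth` can only move labels
from syntagmatic to paradigmatic, never the reverse.
`hierarchy_relation_correlation()` then correlates `q` with the hierarchy
statistic `r` across a collection of networks; within the growth model the
same mechanism is visible directly — raising `p` (more random attachment)
weakens the C(k)–k correlation, which the test suite verifies.

## The synthetic corpus: what a green test establishes

`generate_synthetic_corpus()` emulates exactly the two relational structures
the pipeline is meant to detect: *paradigmatic clusters* (documents draw one
cluster; its member words mix with the cluster's Zipf-weighted context
words, so same-cluster members share context distributions without
co-occurring especially often) and *syntagmatic collocations* (designated
pairs injected as adjacent bigrams at a configured rate, default 0.08 per
position). Defaults (8 clusters of 12 words, 15 collocation pairs, 400
documents of 120 tokens, Zipf exponent 1) are small enough to run in
seconds yet large enough that same-cluster cosines separate cleanly from
cross-cluster ones.

The generator deliberately does *not* emulate: syntax or word order beyond
the injected bigrams, polysemy, document-length variation, word burstiness,
or the scale of a real corpus (hundreds of thousands of documents). A green
test therefore establishes that the pipeline's *mechanics* are correct —
counts, weights, cosines, neighborhood rules, statistics — and that its
measurements respond to planted structure in the right direction. It does
not establish any empirical claim about real corpora; runs on real data
use the same readers (`read_corpus()`, `read_association_norms()`) but are
out of scope for the test suite.

## Degenerate inputs and edge policies

* Empty corpora, missing files, and schema violations in norms tables are
  errors with actionable messages; duplicate (cue, associate) rows are an
  error unless merge-by-sum is requested explicitly.
* Targets absent from a corpus keep all-zero matrix rows (with a warning);
  all-zero rows survive weighting as all-zero rows and yield cosine 0
  against everything by convention.
* Words with no positive cosine get out-degree 0 in the cs rule, with a
  warning; `R` at the extremes behaves as expected (out-degree 1 as
  `R -> 0+`, saturation as `R -> 1-`).
* Degree samples that are all zeros, non-integer, or degenerate (a single
  repeated value, for which the MLE diverges) are rejected.
* `path_stats()` refuses disconnected input instead of silently averaging
  over reachable pairs; apply `largest_component()` first.

## Known limitations

* Cosine computations build a dense n-by-n similarity matrix; fine for the
  few-thousand-word vocabularies the package targets, not for 100k-word
  vocabularies.
* The SVD is dense and exact rather than randomized/sparse.
* The growth model reproduces clustering, component structure and the
  hierarchy statistic of its target regime, but (like the family of models
  it belongs to) it is not designed to match every descriptor at once;
  degree-distribution shape and hierarchy prefer different values of `p`.
* The bootstrap goodness-of-fit test is calibrated (rejection rate near the
  nominal 10% under the null, verified by simulation in the acceptance
  suite) but, like all KS-based tests with estimated parameters, it is
  approximate at small sample sizes.
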