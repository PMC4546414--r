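#' Distributional semantic models
#'
#' Word-context matrices count how often target words occur in contexts,
#' where a context is either a whole document (word-document matrix) or a
#' co-occurring word within a +/- `window` token span (word-word matrix;
#' window 2 is the conventional choice). Matrices can be reweighted by
#' log-entropy tf-idf or by positive pointwise mutual information (ppmi), and
#' smoothed by truncated SVD into a dense semantic space in which relatedness
#' is the cosine between word vectors.
#'
#' Natural logarithms are used throughout; the entropy term of tf-idf divides
#' by `log(n_c)` so the base cancels there, and any fixed base rescales rows
#' uniformly, leaving cosines unchanged.
#'
#' @name dsm
NULL

new_wcm <- function(M, context_type, weighting) {
  structure(list(M = M, context_type = context_type, weighting = weighting),
            class = "word_context_matrix")
}

#' @export
print.word_context_matrix <- function(x, ...) {
  nz <- length(x$M@x)
  cat(sprintf(
    "word_context_matrix: %d words x %d %s contexts (%s; %.2f%% zero)\n",
    nrow(x$M), ncol(x$M), x$context_type, x$weighting,
    100 * (1 - nz / (as.double(nrow(x$M)) * ncol(x$M)))))
  invisible(x)
}

#' Build a word-context frequency matrix from a corpus
#'
#' In document mode, `f[i, j]` is the number of occurrences of target word i
#' in document j. In word mode, `f[i, j]` is the number of co-occurrences of
#' target i with vocabulary word j within `window` positions on either side,
#' inside a document (windows never cross document boundaries). A token does
#' not co-occur with itself at its own position, but distinct positions of the
#' same word type within the window do count, symmetrically.
#'
#' @param corpus a `corpus` object
#' @param targets character vector of target words (matrix rows); targets
#'   absent from the corpus keep an all-zero row with a warning. Defaults to
#'   the full vocabulary.
#' @param context_type `"document"` or `"word"`
#' @param window window half-width for word mode (default 2)
#' @return a `word_context_matrix` holding a sparse count matrix `M` with
#'   dimnames, plus `context_type` and `weighting = "raw"`
#' @export
build_matrix <- function(corpus, targets = NULL,
                         context_type = c("document", "word"), window = 2L) {
  stopifnot(inherits(corpus, "corpus"))
  context_type <- match.arg(context_type)
  stopifnot(window >= 1)
  vocab <- names(corpus$vocabulary)
  if (is.null(targets)) targets <- vocab
  stopifnot(length(targets) > 0)
  missing <- setdiff(targets, vocab)
  if (length(missing) > 0)
    warnf("%d target(s) absent from the corpus keep zero rows (e.g. %s)",
          length(missing), missing[1])

  if (context_type == "document") {
    triples <- lapply(seq_along(corpus$documents), function(d) {
      ti <- match(corpus$documents[[d]], targets)
      ti <- ti[!is.na(ti)]
      if (length(ti) == 0) return(NULL)
      cbind(ti, d)
    })
    triples <- do.call(rbind, triples)
    if (is.null(triples)) triples <- matrix(integer(0), 0, 2)
    M <- Matrix::sparseMatrix(
      i = triples[, 1], j = triples[, 2], x = 1,
      dims = c(length(targets), length(corpus$documents)),
      dimnames = list(targets,
                      sprintf("d%d", seq_along(corpus$documents))))
  } else {
    pair_i <- vector("list", length(corpus$documents) * window)
    pair_j <- vector("list", length(corpus$documents) * window)
    idx <- 0L
    for (doc in corpus$documents) {
      L <- length(doc)
      vi <- match(doc, vocab)
      for (d in seq_len(min(window, L - 1))) {
        a <- vi[seq_len(L - d)]
        b <- vi[seq_len(L - d) + d]
        idx <- idx + 1L
        pair_i[[idx]] <- c(a, b) # count both directions
        pair_j[[idx]] <- c(b, a)
      }
    }
    pi_ <- unlist(pair_i, use.names = FALSE)
    pj_ <- unlist(pair_j, use.names = FALSE)
    ti <- match(vocab[pi_], targets)
    keep <- !is.na(ti)
    M <- Matrix::sparseMatrix(
      i = ti[keep], j = pj_[keep], x = 1,
      dims = c(length(targets), length(vocab)),
      dimnames = list(targets, vocab))
  }
  new_wcm(methods::as(M, "CsparseMatrix"), context_type, "raw")
}

#' Reweight a raw word-context matrix
#'
#' `tfidf` is the log-entropy scheme: `a_ij = log(f_ij + 1) * g_i` with the
#' global weight `g_i = 1 + sum_k P_ik log(P_ik) / log(n_c)` and
#' `P_ij = f_ij / sum_k f_ik`; a word occurring uniformly in every context
#' gets `g_i = 0` and its row vanishes. `ppmi` is positive pointwise mutual
#' information: `a_ij = max(0, log(p_ij / (p_i. p_.j)))`, with zero counts
#' mapped to zero weight (no smoothing constants). Both schemes keep all-zero
#' rows all-zero and never produce negative entries.
#'
#' @param wcm a raw `word_context_matrix`
#' @param scheme `"tfidf"` or `"ppmi"`
#' @return a `word_context_matrix` with updated `weighting`
#' @export
weight_matrix <- function(wcm, scheme = c("tfidf", "ppmi")) {
  stopifnot(inherits(wcm, "word_context_matrix"))
  scheme <- match.arg(scheme)
  if (wcm$weighting != "raw")
    stopf("matrix is already %s-weighted; weighting applies to raw counts",
          wcm$weighting)
  M <- wcm$M
  total <- sum(M@x)
  if (total == 0) stopf("matrix has zero total count")

  if (scheme == "tfidf") {
    n_c <- ncol(M)
    rs <- Matrix::rowSums(M)
    T_ <- methods::as(M, "TsparseMatrix")
    P <- T_@x / rs[T_@i + 1L]
    ent <- rep(0, nrow(M)) # sum_k P log P per row (0 log 0 = 0)
    acc <- tapply(P * log(P), T_@i + 1L, sum)
    ent[as.integer(names(acc))] <- acc
    g <- if (n_c > 1) 1 + ent / log(n_c) else rep(1, nrow(M))
    g[rs == 0] <- 0
    W <- M
    W@x <- log1p(W@x)
    W <- Matrix::Diagonal(x = g) %*% W
    dimnames(W) <- dimnames(M)
  } else {
    rs <- Matrix::rowSums(M)
    cs <- Matrix::colSums(M)
    T_ <- methods::as(M, "TsparseMatrix")
    pmi <- log(T_@x * total / (rs[T_@i + 1L] * cs[T_@j + 1L]))
    keep <- pmi > 0
    W <- Matrix::sparseMatrix(i = T_@i[keep] + 1L, j = T_@j[keep] + 1L,
                              x = pmi[keep], dims = dim(M),
                              dimnames = dimnames(M))
  }
  new_wcm(Matrix::drop0(methods::as(W, "CsparseMatrix")), wcm$context_type,
          scheme)
}

#' Smooth a word-context matrix by truncated SVD
#'
#' Word vectors are the rows of `U_r %*% diag(d_r)` from the rank-`n_r` SVD
#' (the LSA convention), so pairwise cosines equal the cosines of the
#' rank-`n_r` reconstruction rows. If `n_r` exceeds the numerical rank it is
#' reduced with a warning.
#'
#' @param wcm a `word_context_matrix` (any weighting)
#' @param n_r target dimensionality (must not exceed `min(n_w, n_c)`;
#'   300 is the conventional choice at full scale)
#' @return a `semantic_space`: a list with a dense `vectors` matrix (one row
#'   per word) and a `provenance` string
#' @export
smooth_svd <- function(wcm, n_r = 300L) {
  stopifnot(inherits(wcm, "word_context_matrix"))
  M <- as.matrix(wcm$M)
  if (n_r > min(dim(M)))
    stopf("n_r = %d exceeds min(n_w, n_c) = %d", n_r, min(dim(M)))
  if (all(M == 0)) stopf("matrix has no nonzero entries")
  s <- svd(M)
  rank <- sum(s$d > max(dim(M)) * .Machine$double.eps * s$d[1])
  if (n_r > rank) {
    warnf("n_r = %d exceeds matrix rank %d; reduced", n_r, rank)
    n_r <- rank
  }
  V <- s$u[, seq_len(n_r), drop = FALSE] %*%
    diag(s$d[seq_len(n_r)], n_r, n_r)
  rownames(V) <- rownames(M)
  structure(list(vectors = V,
                 provenance = sprintf("%s/%s, n_r = %d", wcm$context_type,
                                      wcm$weighting, n_r)),
            class = "semantic_space")
}

#' @export
print.semantic_space <- function(x, ...) {
  cat(sprintf("semantic_space: %d words x %d dimensions (%s)\n",
              nrow(x$vectors), ncol(x$vectors), x$provenance))
  invisible(x)
}

space_rows <- function(x) {
  if (inherits(x, "semantic_space")) x$vectors
  else if (inherits(x, "word_context_matrix")) x$M
  else stopf("expected a semantic_space or word_context_matrix")
}

#' Cosine similarity between two words
#'
#' Standard cosine of the two row vectors; a zero vector against anything is
#' 0 by convention (with a message).
#'
#' @param x a `semantic_space` or `word_context_matrix`
#' @param w1,w2 words (row labels)
#' @return similarity in `[-1, 1]`
#' @export
cosine <- function(x, w1, w2) {
  V <- space_rows(x)
  for (w in c(w1, w2))
    if (!w %in% rownames(V)) stopf("unknown word: %s", w)
  a <- as.numeric(V[w1, ])
  b <- as.numeric(V[w2, ])
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    message("zero vector in cosine(); returning 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}

#' All pairwise cosine similarities
#'
#' @inheritParams cosine
#' @return dense symmetric matrix of cosines with word dimnames; rows with
#'   zero norm yield 0 cosines
#' @export
cosine_matrix <- function(x) {
  V <- space_rows(x)
  nrm <- sqrt(Matrix::rowSums(V^2))
  nrm[nrm == 0] <- Inf # zero vectors -> cosine 0
  S <- Matrix::tcrossprod(Matrix::Diagonal(x = 1 / nrm) %*% V)
  S <- as.matrix(S)
  dimnames(S) <- list(rownames(V), rownames(V))
  S
}
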