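#' Corpora and association norms
#'
#' A corpus is an ordered collection of tokenized documents plus a vocabulary
#' with frequencies. Corpora are stored as UTF-8 plain text, one
#' whitespace-tokenized document per line. Association norms are delimited
#' tables of (cue, associate, participant count). A synthetic-corpus
#' generator provides controlled paradigmatic clusters (words sharing
#' contexts) and syntagmatic collocation pairs (words co-occurring within a
#' two-token window) so the downstream pipeline is testable without external
#' corpus downloads.
#'
#' @name corpusio
NULL

new_corpus <- function(documents) {
  tokens <- unlist(documents, use.names = FALSE)
  if (length(tokens) == 0) stopf("empty corpus")
  vocab <- table(tokens)
  structure(list(
    documents = documents,
    vocabulary = stats::setNames(as.integer(vocab), names(vocab))),
    class = "corpus")
}

#' @export
print.corpus <- function(x, ...) {
  cat(sprintf("corpus: %d documents, %d word types, %d tokens\n",
              length(x$documents), length(x$vocabulary),
              sum(x$vocabulary)))
  invisible(x)
}

#' Read a plain-text corpus
#'
#' One document per line, whitespace-tokenized. Tokenization is deliberately
#' minimal (no stemming or stop-listing) so that all downstream counts stay
#' auditable.
#'
#' @param path file path
#' @param lowercase fold tokens to lower case (default TRUE)
#' @param min_token_length drop tokens shorter than this (default 1)
#' @return a `corpus` object with `documents` (list of character vectors) and
#'   `vocabulary` (named integer frequencies)
#' @export
read_corpus <- function(path, lowercase = TRUE, min_token_length = 1L) {
  if (!file.exists(path)) stopf("corpus file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (lowercase) lines <- tolower(lines)
  docs <- strsplit(trimws(lines), "\\s+")
  docs <- lapply(docs, function(d) d[nzchar(d) & nchar(d) >= min_token_length])
  docs <- docs[lengths(docs) > 0]
  if (length(docs) == 0) stopf("empty corpus: %s", path)
  new_corpus(docs)
}

#' Write a corpus back to plain text
#'
#' Inverse of [read_corpus()]: token sequences are reproduced exactly.
#'
#' @param corpus a `corpus` object
#' @param path output file path
#' @export
write_corpus <- function(corpus, path) {
  stopifnot(inherits(corpus, "corpus"))
  writeLines(vapply(corpus$documents, paste, character(1), collapse = " "),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read an association-norms table
#'
#' Reads a delimited file with a header naming the cue, associate and
#' participant-count columns. The count column is preserved so that the
#' standard "listed by at least two participants" edge filter can be applied
#' when the network is built (see [build_association_network()]).
#'
#' @param path CSV or TSV file (delimiter sniffed from the header line)
#' @param cue_col,assoc_col,count_col column names (defaults `cue`,
#'   `associate`, `count`)
#' @param duplicates what to do with repeated (cue, associate) rows:
#'   `"error"` (default; norms should arrive pre-aggregated) or `"sum"`
#' @return a data frame of class `association_table` with columns `cue`,
#'   `associate`, `count` (and `strength` when present in the file)
#' @export
read_association_norms <- function(path, cue_col = "cue",
                                   assoc_col = "associate",
                                   count_col = "count",
                                   duplicates = c("error", "sum")) {
  duplicates <- match.arg(duplicates)
  if (!file.exists(path)) stopf("norms file not found: %s", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (col in c(cue_col, assoc_col, count_col))
    if (!col %in% names(df))
      stopf("norms file lacks required column '%s' (columns present: %s)",
            col, paste(names(df), collapse = ", "))
  cnt <- df[[count_col]]
  if (!is.numeric(cnt) || any(!is.finite(cnt)) || any(cnt != floor(cnt)))
    stopf("column '%s' must contain integer participant counts", count_col)
  if (any(cnt < 1)) stopf("participant counts must be >= 1")
  out <- data.frame(cue = as.character(df[[cue_col]]),
                    associate = as.character(df[[assoc_col]]),
                    count = as.integer(cnt),
                    stringsAsFactors = FALSE)
  if ("strength" %in% names(df)) out$strength <- df$strength
  key <- paste(out$cue, out$associate, sep = "\r")
  if (anyDuplicated(key)) {
    if (duplicates == "error")
      stopf("duplicate (cue, associate) rows; pass duplicates = \"sum\" to merge")
    agg <- aggregate(list(count = out$count), list(key = key), sum)
    first <- out[!duplicated(key), c("cue", "associate")]
    out <- cbind(first, count = agg$count[match(key[!duplicated(key)], agg$key)])
  }
  class(out) <- c("association_table", "data.frame")
  out
}

#' Configuration for the synthetic-corpus generator
#'
#' Defaults describe a small but structured world: a few hundred documents of
#' ~100 tokens, several paradigmatic clusters whose member words share the
#' same context-word distribution, a pool of Zipf-distributed context words
#' per cluster, and a set of collocation pairs injected as adjacent bigrams.
#'
#' @param n_clusters number of paradigmatic clusters
#' @param words_per_cluster member words per cluster
#' @param n_collocation_pairs number of syntagmatic collocation pairs
#' @param n_documents,doc_length corpus shape (tokens per document >= 2)
#' @param zipf_exponent skew of the context-word frequency distribution
#'   within each cluster (0 = uniform)
#' @param collocation_rate probability per token position that a collocation
#'   bigram is injected
#' @param seed RNG seed (generation is deterministic given the seed)
#' @return a list of class `synth_corpus_config`
#' @export
synth_corpus_config <- function(n_clusters = 8L, words_per_cluster = 12L,
                                n_collocation_pairs = 15L,
                                n_documents = 400L, doc_length = 120L,
                                zipf_exponent = 1, collocation_rate = 0.08,
                                seed = 1L) {
  stopifnot(n_clusters >= 1, words_per_cluster >= 1, n_collocation_pairs >= 1,
            n_documents >= 1, doc_length >= 2, zipf_exponent >= 0,
            collocation_rate >= 0, collocation_rate <= 1)
  structure(as.list(environment()), class = "synth_corpus_config")
}

#' Generate a synthetic corpus with paradigmatic and syntagmatic structure
#'
#' Mixture model: each document draws one cluster; tokens are then drawn as a
#' mix of that cluster's member words and its Zipf-weighted context words, so
#' same-cluster members co-occur with similar context words (paradigmatic
#' structure). With probability `collocation_rate` per position a collocation
#' pair is emitted as an adjacent bigram, so those pairs co-occur within a
#' two-token window far more often than chance (syntagmatic structure). The
#' total token count is exactly `n_documents * doc_length`.
#'
#' @param config a [synth_corpus_config()]
#' @return a `corpus` object
#' @export
generate_synthetic_corpus <- function(config) {
  stopifnot(inherits(config, "synth_corpus_config"))
  cfg <- config
  n_ctx <- cfg$words_per_cluster # context pool size per cluster
  vocab_size <- cfg$n_clusters * (cfg$words_per_cluster + n_ctx) +
    2 * cfg$n_collocation_pairs
  if (vocab_size > cfg$n_documents * cfg$doc_length)
    stopf("vocabulary (%d types) exceeds the token budget (%d tokens)",
          vocab_size, cfg$n_documents * cfg$doc_length)

  members <- lapply(seq_len(cfg$n_clusters), function(cl)
    sprintf("w%d_%d", cl, seq_len(cfg$words_per_cluster)))
  contexts <- lapply(seq_len(cfg$n_clusters), function(cl)
    sprintf("ctx%d_%d", cl, seq_len(n_ctx)))
  ctx_prob <- seq_len(n_ctx)^(-cfg$zipf_exponent)
  ctx_prob <- ctx_prob / sum(ctx_prob)
  col_a <- sprintf("col%d_a", seq_len(cfg$n_collocation_pairs))
  col_b <- sprintf("col%d_b", seq_len(cfg$n_collocation_pairs))

  with_seed(cfg$seed, {
    docs <- vector("list", cfg$n_documents)
    for (d in seq_len(cfg$n_documents)) {
      cl <- sample.int(cfg$n_clusters, 1)
      toks <- character(cfg$doc_length)
      i <- 1L
      while (i <= cfg$doc_length) {
        if (i < cfg$doc_length && runif(1) < cfg$collocation_rate) {
          p <- sample.int(cfg$n_collocation_pairs, 1)
          toks[i] <- col_a[p]
          toks[i + 1L] <- col_b[p]
          i <- i + 2L
        } else {
          toks[i] <- if (runif(1) < 0.5)
            sample(members[[cl]], 1)
          else
            sample(contexts[[cl]], 1, prob = ctx_prob)
          i <- i + 1L
        }
      }
      docs[[d]] <- toks
    }
    new_corpus(docs)
  })
}
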