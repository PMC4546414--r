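test_that("build_matrix counts document contexts", {
  corp <- corpus_from_docs("a b a", "b")
  wcm <- build_matrix(corp, context_type = "document")
  expect_equal(wcm$M["a", "d1"], 2)
  expect_equal(wcm$M["b", "d1"], 1)
  expect_equal(wcm$M["b", "d2"], 1)
  expect_equal(wcm$M["a", "d2"], 0)
})

test_that("build_matrix counts word contexts within the window, symmetrically", {
  # hand count: in [a, b, c] with window 2, a co-occurs once with b and c
  wcm <- build_matrix(corpus_from_docs("a b c"), targets = "a",
                      context_type = "word", window = 2)
  expect_equal(wcm$M["a", "b"], 1)
  expect_equal(wcm$M["a", "c"], 1)

  # [a, a]: the two positions co-occur, counted in both directions
  wcm2 <- build_matrix(corpus_from_docs("a a"), context_type = "word")
  expect_equal(wcm2$M["a", "a"], 2)

  # windows never cross document boundaries
  wcm3 <- build_matrix(corpus_from_docs("a b", "c d"), context_type = "word")
  expect_equal(wcm3$M["a", "c"], 0)

  # full-vocabulary word-word counts are symmetric
  corp <- generate_synthetic_corpus(synth_corpus_config(
    n_clusters = 2, words_per_cluster = 4, n_collocation_pairs = 2,
    n_documents = 20, doc_length = 30, seed = 3))
  W <- build_matrix(corp, context_type = "word")$M
  expect_equal(as.matrix(W), t(as.matrix(W)))

  # absent targets keep a zero row with a warning
  expect_warning(w4 <- build_matrix(corpus_from_docs("a b"),
                                    targets = c("a", "zzz"),
                                    context_type = "document"),
                 "absent")
  expect_equal(sum(w4$M["zzz", ]), 0)
})

test_that("tf-idf matches hand computation (natural log, entropy weight)", {
  # row 1 occurs only in context 1 (f = 3): entropy term 0 -> a = log 4
  # row 2 occurs uniformly in both contexts: weight 1 + (-1) = 0 -> zero row
  corp <- corpus_from_docs("a a a b b", "b b")
  wcm <- build_matrix(corp, context_type = "document")
  tf <- weight_matrix(wcm, "tfidf")
  expect_equal(tf$M["a", "d1"], log(4), tolerance = 1e-12)
  expect_equal(tf$M["a", "d2"], 0)
  expect_equal(sum(abs(tf$M["b", ])), 0)
  expect_identical(tf$weighting, "tfidf")
})

test_that("ppmi matches the hand-computed 2x2 example", {
  # counts [[2, 0], [1, 1]] -> ppmi [[log(4/3), 0], [0, log 2]]
  corp <- corpus_from_docs("a a b", "b")
  wcm <- build_matrix(corp, context_type = "document")
  pp <- weight_matrix(wcm, "ppmi")
  expect_equal(pp$M["a", "d1"], log(4 / 3), tolerance = 1e-12)
  expect_equal(pp$M["a", "d2"], 0)
  expect_equal(pp$M["b", "d1"], 0)
  expect_equal(pp$M["b", "d2"], log(2), tolerance = 1e-12)
})

test_that("weighting is non-negative, keeps zero rows zero, and stacks error", {
  corp <- generate_synthetic_corpus(synth_corpus_config(
    n_clusters = 3, words_per_cluster = 4, n_collocation_pairs = 3,
    n_documents = 30, doc_length = 40, seed = 5))
  wcm <- build_matrix(corp, context_type = "word")
  for (scheme in c("tfidf", "ppmi")) {
    w <- weight_matrix(wcm, scheme)
    expect_true(all(w$M@x >= 0))
    # ppmi never densifies the stored representation relative to raw
    if (scheme == "ppmi") expect_lte(length(w$M@x), length(wcm$M@x))
    expect_error(weight_matrix(w, scheme), "already")
  }
})

test_that("smooth_svd preserves cosines at full rank and rank-1", {
  set.seed(8)
  A <- matrix(rpois(20 * 12, 2), 20, 12)
  rownames(A) <- sprintf("w%02d", 1:20)
  wcm <- semnetkit:::new_wcm(methods::as(Matrix::Matrix(A, sparse = TRUE),
                                         "CsparseMatrix"), "document", "raw")
  # full rank: cosines equal raw-matrix row cosines
  sp <- smooth_svd(wcm, n_r = 12)
  raw_cos <- cosine_matrix(wcm)
  expect_equal(cosine_matrix(sp), raw_cos, tolerance = 1e-8)

  # rank-1 input: any n_r >= 1 keeps cosines in {-1, +1}
  B <- outer(c(1, 2, 3), c(2, 0, 1))
  rownames(B) <- c("p", "q", "r")
  w1 <- semnetkit:::new_wcm(methods::as(Matrix::Matrix(B, sparse = TRUE),
                                        "CsparseMatrix"), "document", "raw")
  expect_warning(sp1 <- smooth_svd(w1, n_r = 3), "rank")
  expect_equal(abs(cosine(sp1, "p", "q")), 1, tolerance = 1e-10)
})

test_that("truncated SVD agrees with a dense full-decomposition oracle", {
  set.seed(9)
  A <- matrix(rpois(20 * 30, 1.5), 20, 30)
  rownames(A) <- sprintf("w%02d", 1:20)
  wcm <- semnetkit:::new_wcm(methods::as(Matrix::Matrix(A, sparse = TRUE),
                                         "CsparseMatrix"), "document", "raw")
  sp <- smooth_svd(wcm, n_r = 5)
  # oracle: cosines of the rank-5 reconstruction rows from a dense SVD
  s <- svd(A)
  R5 <- s$u[, 1:5] %*% diag(s$d[1:5]) %*% t(s$v[, 1:5])
  oracle <- R5 %*% t(R5) / tcrossprod(sqrt(rowSums(R5^2)))
  got <- cosine_matrix(sp)
  expect_equal(unname(got), unname(as.matrix(oracle)), tolerance = 1e-6)

  # reconstruction energy is non-decreasing in n_r
  energies <- vapply(1:6, function(r)
    sum((s$u[, 1:r, drop = FALSE] %*% diag(s$d[1:r], r, r))^2), numeric(1))
  expect_true(all(diff(energies) >= 0))

  expect_error(smooth_svd(wcm, n_r = 21), "exceeds")
})

test_that("cosine handles identity, orthogonality and hand example", {
  V <- rbind(u = c(1, 1, 0), v = c(1, 0, 0), w = c(0, 0, 1), z = c(0, 0, 0))
  sp <- structure(list(vectors = V, provenance = "fixture"),
                  class = "semantic_space")
  expect_equal(cosine(sp, "u", "u"), 1)
  expect_equal(cosine(sp, "v", "w"), 0)
  expect_equal(cosine(sp, "u", "v"), 1 / sqrt(2), tolerance = 1e-12)
  expect_message(z <- cosine(sp, "z", "u"), "zero vector")
  expect_equal(z, 0)
  expect_error(cosine(sp, "u", "nope"), "unknown word")
})
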