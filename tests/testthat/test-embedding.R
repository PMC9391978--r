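test_that("co-occurrence counts documents, not mentions", {
  # A in {d1,d2}, B in {d2,d3}, 4 docs; A mentioned twice in d1
  docs <- list(
    annotated_document("d1", "toy", list(mk_mention("A"), mk_mention("A"),
                                         mk_mention("COND"))),
    mk_doc("d2", c("A", "B", "COND")),
    mk_doc("d3", c("B", "COND")),
    mk_doc("d4", "COND")
  )
  cfg <- toy_cfg(condition_ids = "COND")
  v <- build_vocabulary(docs, cfg)
  co <- build_cooccurrence(docs, v)
  cm <- as.matrix(co$counts)
  expect_equal(cm["A", "B"], 1)
  expect_equal(cm["A", "A"], 2)   # diagonal = document frequency
  expect_equal(cm["B", "B"], 2)
  expect_equal(cm["A", "COND"], 2)  # double mention in d1 counts once
  expect_equal(co$n_docs, 4L)
  expect_true(Matrix::isSymmetric(co$counts))
})

test_that("disjoint concepts have zero off-diagonal counts and unknown mentions are ignored", {
  docs <- list(mk_doc("d1", c("COND", "A", "GHOST")),
               mk_doc("d2", c("COND", "B")))
  cfg <- toy_cfg(condition_ids = "COND", blocklist = "GHOST")
  v <- build_vocabulary(docs, cfg)
  co <- build_cooccurrence(docs, v)
  expect_false("GHOST" %in% rownames(co$counts))
  expect_equal(as.numeric(co$counts["A", "B"]), 0)
  expect_error(build_cooccurrence(list(), v), "zero documents")
})

test_that("PPMI reproduces the hand-worked two-concept cases", {
  # independence: A in {d1,d2}, B in {d2,d3}, N=4 -> PMI log(1) = 0
  docs <- list(mk_doc("d1", c("A", "X")), mk_doc("d2", c("A", "B")),
               mk_doc("d3", c("B", "X")), mk_doc("d4", "X"))
  cfg <- toy_cfg(condition_ids = "X")
  v <- build_vocabulary(docs, cfg)
  pp <- compute_ppmi(build_cooccurrence(docs, v))
  expect_equal(as.numeric(pp$values["A", "B"]), 0)

  # perfect association: A and B both in exactly {d1,d2}, N=4 -> ln 2
  docs2 <- list(mk_doc("d1", c("A", "B")), mk_doc("d2", c("A", "B")),
                mk_doc("d3", "X"), mk_doc("d4", "X"))
  v2 <- build_vocabulary(docs2, cfg)
  pp2 <- compute_ppmi(build_cooccurrence(docs2, v2))
  expect_equal(as.numeric(pp2$values["A", "B"]), log(2))

  # never co-occurring: exactly 0, no -Inf, no warning
  expect_silent(pp3 <- compute_ppmi(build_cooccurrence(
    list(mk_doc("d1", c("A", "X")), mk_doc("d2", c("B", "X"))),
    build_vocabulary(list(mk_doc("d1", c("A", "X")),
                          mk_doc("d2", c("B", "X"))), cfg))))
  expect_equal(as.numeric(pp3$values["A", "B"]), 0)
})

test_that("vectorized PPMI equals the scalar-loop oracle on random corpora", {
  set.seed(101)
  for (rep in 1:25) {
    co <- random_cooc(sample(3:12, 1), sample(5:40, 1),
                      density = runif(1, 0.2, 0.7))
    got <- as.matrix(compute_ppmi(co)$values)
    want <- ppmi_oracle(co$counts, co$n_docs)
    expect_lt(max(abs(got - unname(want))), 1e-10)
  }
})

test_that("PPMI is symmetric, non-negative, and zero at saturation", {
  set.seed(7)
  co <- random_cooc(10, 30)
  pp <- compute_ppmi(co)
  expect_true(Matrix::isSymmetric(pp$values))
  expect_gte(if (length(pp$values@x)) min(pp$values@x) else 0, 0)

  # every concept in every document: perfect independence, PPMI == 0
  docs <- mk_corpus(setNames(rep(list(c("COND", "A", "B")), 5),
                             paste0("d", 1:5)))
  cfg <- toy_cfg(condition_ids = "COND")
  v <- build_vocabulary(docs, cfg)
  pp_sat <- compute_ppmi(build_cooccurrence(docs, v))
  expect_equal(sum(abs(pp_sat$values)), 0)
})

test_that("keep_diagonal retains clamped self-information", {
  set.seed(8)
  co <- random_cooc(6, 25)
  pp <- compute_ppmi(co, keep_diagonal = TRUE)
  df <- Matrix::diag(co$counts)
  want <- pmax(log((df / co$n_docs) / (df / co$n_docs)^2), 0)
  expect_equal(as.numeric(Matrix::diag(pp$values)), unname(want))
  expect_equal(sum(abs(Matrix::diag(compute_ppmi(co)$values))), 0)
})

test_that("rank-1 matrices are recovered exactly at k = 1", {
  v <- c(1, 2, 3, 0.5)
  M <- tcrossprod(v)
  emb <- embed_svd(mk_ppmi(M), k = 1)
  expect_equal(emb$k, 1L)
  # for a symmetric PSD matrix V = U, so M ~ (U1 s1) U1' = E E' / s1
  recon <- tcrossprod(emb$vectors) / emb$singular_values[1]
  expect_lt(max(abs(recon - M)), 1e-8)
})

test_that("requested k beyond the spectrum clamps without failure", {
  set.seed(21)
  co <- random_cooc(5, 20)
  emb <- embed_svd(compute_ppmi(co), k = 300)
  expect_lte(emb$k, 5L)
  expect_identical(ncol(emb$vectors), emb$k)
  expect_true(all(diff(emb$singular_values) <= 1e-12))
  expect_error(embed_svd(mk_ppmi(matrix(0, 3, 3))), "identically zero")
  expect_error(embed_svd(compute_ppmi(co), k = 0), "k must be")
})

test_that("full-rank embeddings preserve pairwise row cosines of the input", {
  set.seed(31)
  A <- matrix(runif(64), 8, 8)
  M <- abs(A + t(A)); diag(M) <- 0  # symmetric, non-negative, PPMI-like
  emb <- embed_svd(mk_ppmi(M), k = 8)
  cos_of <- function(X) {
    nr <- sqrt(rowSums(X^2))
    tcrossprod(X / nr)
  }
  # dense full-SVD oracle: row cosines of M itself (V is orthogonal)
  s <- svd(M)
  expect_lt(max(abs(cos_of(emb$vectors) - cos_of(M))), 1e-6)
  expect_equal(sort(emb$singular_values), sort(s$d), tolerance = 1e-8)
})

test_that("the seeded randomized path agrees with the exact path", {
  set.seed(77)
  A <- matrix(runif(900), 30, 30)
  M <- abs(A + t(A)); diag(M) <- 0
  pp <- mk_ppmi(M)
  exact <- embed_svd(pp, k = 5, exact_limit = 2000)
  rnd1 <- embed_svd(pp, k = 5, exact_limit = 10, seed = 42)
  rnd2 <- embed_svd(pp, k = 5, exact_limit = 10, seed = 42)
  expect_identical(rnd1$vectors, rnd2$vectors)  # seeded determinism
  expect_equal(rnd1$singular_values, exact$singular_values,
               tolerance = 1e-6)
  # the geometry that matters downstream: pairwise row cosines agree
  cos_of <- function(X) tcrossprod(X / sqrt(rowSums(X^2)))
  expect_lt(max(abs(cos_of(rnd1$vectors) - cos_of(exact$vectors))), 1e-3)
})

test_that("matrices and embeddings serialize with their vocabulary sidecar", {
  set.seed(13)
  co <- random_cooc(6, 20)
  pp <- compute_ppmi(co)
  d <- withr::local_tempdir()
  write_sparse_matrix(pp, file.path(d, "ppmi.mtx"))
  m <- Matrix::readMM(file.path(d, "ppmi.mtx"))
  expect_equal(max(abs(as.matrix(m) - unname(as.matrix(pp$values)))), 0)
  voc <- read_vocabulary(file.path(d, "ppmi.mtx.vocab.tsv"))
  expect_identical(voc$concept_id, pp$vocab$concept_id)

  emb <- embed_svd(pp, k = 3)
  write_embedding(emb, file.path(d, "emb.tsv"))
  back <- utils::read.table(file.path(d, "emb.tsv"), header = TRUE, sep = "\t")
  expect_identical(back$concept_id, rownames(emb$vectors))
  expect_equal(unname(as.matrix(back[, -1])), unname(emb$vectors),
               tolerance = 1e-12)
})
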