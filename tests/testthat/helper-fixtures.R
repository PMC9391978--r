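# fixture builders shared across test files; everything is generated in code

mk_mention <- function(id, score = 0.9, types = "finding", name = id) {
  concept_mention(id, name, types, score)
}

# document with one mention per concept id, all at the same score/type
mk_doc <- function(doc_id, ids, source = "toy", score = 0.9,
                   types = "finding") {
  annotated_document(doc_id, source,
                     lapply(ids, mk_mention, score = score, types = types))
}

# corpus from a named list: doc_id -> character vector of concept ids
mk_corpus <- function(assignments, source = "toy", score = 0.9) {
  out <- lapply(names(assignments), function(d) {
    mk_doc(d, assignments[[d]], source = source, score = score)
  })
  out
}

toy_cfg <- function(min_doc_count = 1L, ...) {
  filter_config(score_cutoff = 0.5, min_doc_count = min_doc_count,
                allowed_semantic_types = c("finding", "behavior",
                                           "mental or behavioral dysfunction"),
                ...)
}

# build a ppmi_matrix container around an arbitrary symmetric matrix,
# for exercising embed_svd in isolation
mk_ppmi <- function(M, ids = NULL) {
  n <- nrow(M)
  if (is.null(ids)) ids <- sprintf("X%02d", seq_len(n))
  dimnames(M) <- list(ids, ids)
  vocab <- structure(
    tibble::tibble(concept_id = ids, name = ids, semantic_type = "finding",
                   index = seq_len(n), doc_count = 1L, is_condition = FALSE),
    class = c("concept_vocabulary", class(tibble::tibble())),
    n = n, n_docs = n, score_cutoff = 0
  )
  structure(list(values = Matrix::Matrix(M, sparse = TRUE), vocab = vocab),
            class = "ppmi_matrix")
}

# independent scalar-loop oracle for the PPMI transform (Eq-by-eq, no
# vectorization shared with the implementation)
ppmi_oracle <- function(counts, N) {
  counts <- as.matrix(counts)
  n <- nrow(counts)
  df <- diag(counts)
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      cij <- counts[i, j]
      if (cij > 0) {
        pmi <- log((cij / N) / ((df[i] / N) * (df[j] / N)))
        out[i, j] <- max(pmi, 0)
      }
    }
  }
  out
}

# random document-concept incidence with guaranteed nonzero column sums,
# returned as a cooccurrence_matrix
random_cooc <- function(n_concepts, n_docs, density = 0.3) {
  repeat {
    X <- matrix(runif(n_docs * n_concepts) < density, n_docs, n_concepts)
    if (all(colSums(X) > 0)) break
  }
  ids <- sprintf("C%03d", seq_len(n_concepts))
  counts <- Matrix::forceSymmetric(Matrix::crossprod(
    Matrix::Matrix(X * 1, sparse = TRUE)))
  dimnames(counts) <- list(ids, ids)
  vocab <- structure(
    tibble::tibble(concept_id = ids, name = ids, semantic_type = "finding",
                   index = seq_len(n_concepts),
                   doc_count = as.integer(colSums(X)), is_condition = FALSE),
    class = c("concept_vocabulary", class(tibble::tibble())),
    n = n_concepts, n_docs = n_docs, score_cutoff = 0
  )
  structure(list(counts = counts, n_docs = n_docs, vocab = vocab),
            class = "cooccurrence_matrix")
}

# fabricate a relatedness_table directly from a named relatedness vector
mk_rel_table <- function(rel, condition_id = "C0000", source = "a",
                         freq = NULL) {
  ids <- names(rel)
  if (is.null(freq)) freq <- rep(0.5, length(ids))
  structure(
    tibble::tibble(concept_id = ids, name = ids, semantic_type = "finding",
                   relatedness = unname(rel), frequency = freq),
    class = c("relatedness_table", class(tibble::tibble())),
    condition_id = condition_id, source = source
  )
}

# a fabricated ranked_selection with n_types full lists of n_per concepts
mk_selection <- function(n_types = 3L, n_per = 25L, source = "toy",
                         condition_id = "COND") {
  sel <- lapply(seq_len(n_types), function(t) {
    ids <- sprintf("T%dC%02d", t, seq_len(n_per))
    tibble::tibble(concept_id = ids, name = ids,
                   relatedness = seq(0.9, 0.1, length.out = n_per),
                   frequency = seq(0.8, 0.2, length.out = n_per),
                   rank = seq_len(n_per))
  })
  names(sel) <- sprintf("type%d", seq_len(n_types))
  structure(sel, class = "ranked_selection", condition_id = condition_id,
            source = source, top_k = n_per)
}

# end-to-end convenience: default synthetic corpus -> relatedness table
run_synthetic_relatedness <- function(seed, n_docs = 1000L, ...) {
  spec <- synthetic_spec(n_docs = n_docs, seed = seed, ...)
  g <- generate_corpus(spec)
  cfg <- filter_config(condition_ids = spec$condition_ids)
  docs <- filter_condition_documents(g$docs, cfg)
  vocab <- build_vocabulary(docs, cfg)
  emb <- embed_svd(compute_ppmi(build_cooccurrence(docs, vocab)), k = 300)
  list(rel = relatedness_table(emb, docs, spec$condition_id),
       ground_truth = g$ground_truth, docs = docs, vocab = vocab, emb = emb,
       spec = spec)
}
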