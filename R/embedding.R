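#' Build the document-level co-occurrence matrix
#'
#' Counts, for every pair of vocabulary concepts, the number of documents in
#' which both appear. Counting is presence-based: a concept mentioned five
#' times in one document contributes one, not five, to every pair it sits in,
#' so repeated mentions cannot inflate co-occurrence. The diagonal holds each
#' concept's document frequency. Mentions of concepts outside the vocabulary
#' (or below the score cutoff the vocabulary was built with) are ignored.
#'
#' @param docs Filtered documents the vocabulary was built from.
#' @param vocab A `concept_vocabulary` from [build_vocabulary()].
#' @return A list of class `cooccurrence_matrix` with `counts` (sparse
#'   symmetric n x n [Matrix::Matrix] in vocabulary index order), `n_docs`,
#'   and `vocab`.
#' @export
build_cooccurrence <- function(docs, vocab) {
  if (length(docs) == 0L) stopf("cannot count co-occurrence over zero documents")
  cutoff <- attr(vocab, "score_cutoff") %||% 0
  flat <- flatten_mentions(docs)
  flat <- flat[flat$score > cutoff & flat$concept_id %in% vocab$concept_id, ]
  flat <- dplyr::distinct(flat, .data$doc_id, .data$concept_id)
  doc_ids <- vapply(docs, `[[`, character(1), "doc_id")
  # documents x concepts binary incidence; crossprod gives pair counts
  X <- Matrix::sparseMatrix(
    i = match(flat$doc_id, doc_ids),
    j = match(flat$concept_id, vocab$concept_id),
    x = 1,
    dims = c(length(docs), nrow(vocab)),
    dimnames = list(doc_ids, vocab$concept_id)
  )
  counts <- Matrix::forceSymmetric(Matrix::crossprod(X))
  structure(list(counts = counts, n_docs = length(docs), vocab = vocab),
            class = "cooccurrence_matrix")
}

#' Transform co-occurrence counts to positive pointwise mutual information
#'
#' For concepts \eqn{c_i, c_j} with document-proportion probabilities
#' \eqn{p(c_i) = n_i / N} and joint \eqn{p(c_i, c_j) = n_{ij} / N},
#' \deqn{PMI(c_i, c_j) = \log\frac{p(c_i, c_j)}{p(c_i)\,p(c_j)}}
#' (natural log) and \eqn{PPMI = \max(PMI, 0)}. Pairs that never co-occur
#' map to 0 rather than \eqn{-\infty}, so the result stays sparse. The
#' diagonal is zeroed by default so a concept's vector reflects its
#' neighbourhood rather than its own frequency.
#'
#' Downstream cosine relatedness is invariant to the log base (a positive
#' rescaling of the whole matrix), so the choice of natural log is pure
#' convention.
#'
#' @param cooc A `cooccurrence_matrix`.
#' @param keep_diagonal Keep the (clamped) self-PMI on the diagonal instead
#'   of zeroing it. Default `FALSE`.
#' @return A list of class `ppmi_matrix` with `values` (sparse symmetric
#'   non-negative n x n matrix) and `vocab`.
#' @export
compute_ppmi <- function(cooc, keep_diagonal = FALSE) {
  stopifnot(inherits(cooc, "cooccurrence_matrix"))
  N <- cooc$n_docs
  if (N < 1L) stopf("co-occurrence matrix covers zero documents")
  df <- Matrix::diag(cooc$counts)
  if (any(df == 0)) {
    stopf("concept(s) with zero document frequency: %s",
          paste(cooc$vocab$concept_id[df == 0], collapse = ", "))
  }
  trip <- Matrix::mat2triplet(as(cooc$counts, "generalMatrix"))
  keep <- trip$x > 0 & (keep_diagonal | trip$i != trip$j)
  i <- trip$i[keep]; j <- trip$j[keep]; cnt <- trip$x[keep]
  pmi <- log(cnt * N / (df[i] * df[j]))
  pos <- pmi > 0
  values <- Matrix::sparseMatrix(
    i = i[pos], j = j[pos], x = pmi[pos],
    dims = dim(cooc$counts), dimnames = dimnames(cooc$counts)
  )
  values <- Matrix::forceSymmetric(values)
  structure(list(values = values, vocab = cooc$vocab),
            class = "ppmi_matrix")
}

# Seeded randomized range-finder SVD (Gaussian sketch, power iterations,
# small-matrix LAPACK finish). Deterministic for a fixed seed.
randomized_svd <- function(A, k, seed, n_oversample = 10L, n_iter = 4L) {
  n <- ncol(A)
  l <- min(n, k + n_oversample)
  with_local_seed(seed, {
    omega <- matrix(rnorm(n * l), n, l)
    Y <- as.matrix(A %*% omega)
    Q <- qr.Q(qr(Y))
    for (it in seq_len(n_iter)) {
      Z <- qr.Q(qr(as.matrix(Matrix::crossprod(A, Q))))
      Q <- qr.Q(qr(as.matrix(A %*% Z)))
    }
    B <- as.matrix(Matrix::crossprod(Q, A))
    s <- svd(B)
    list(d = s$d[seq_len(min(k, length(s$d)))],
         u = (Q %*% s$u)[, seq_len(min(k, ncol(s$u))), drop = FALSE],
         v = s$v[, seq_len(min(k, ncol(s$v))), drop = FALSE])
  })
}

#' Embed concepts by truncated SVD of the PPMI matrix
#'
#' Factorizes the PPMI matrix \eqn{M \approx U_k S_k V_k^T} and returns the
#' n x k embedding \eqn{U_k S_k}, one row per concept in vocabulary order.
#' Singular values are non-increasing; if `k` exceeds the number of
#' numerically positive singular values (or the vocabulary size), the
#' effective dimension is clamped and reported in the result. Column signs
#' follow the convention that the largest-magnitude entry of each left
#' singular vector is positive, which combined with a seeded sketch makes
#' the embedding fully reproducible.
#'
#' An exact LAPACK SVD is used up to `exact_limit` concepts; beyond that a
#' seeded randomized SVD (Gaussian sketch with power iterations) is used.
#'
#' @param ppmi A `ppmi_matrix`.
#' @param k Target dimension. Default 300.
#' @param exact_limit Largest n for which the dense exact SVD is taken.
#'   Default 2000.
#' @param seed Seed for the randomized path. Default 1.
#' @return A list of class `embedding_matrix` with `vectors` (dense n x k
#'   matrix, rownames = concept ids), `k` (effective), `singular_values`,
#'   and `vocab`.
#' @export
embed_svd <- function(ppmi, k = 300L, exact_limit = 2000L, seed = 1L) {
  stopifnot(inherits(ppmi, "ppmi_matrix"))
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stopf("k must be >= 1")
  n <- nrow(ppmi$values)
  if (all(ppmi$values@x == 0) || length(ppmi$values@x) == 0L) {
    stopf("PPMI matrix is identically zero: no co-occurrence structure to embed")
  }
  k_req <- min(k, n)
  if (n <= exact_limit) {
    s <- svd(as.matrix(ppmi$values), nu = k_req, nv = k_req)
    d <- s$d[seq_len(k_req)]
    u <- s$u
  } else {
    s <- randomized_svd(ppmi$values, k_req, seed = seed)
    d <- s$d
    u <- s$u
  }
  pos <- d > max(d) * 1e-12
  k_eff <- max(1L, sum(pos))
  d <- d[seq_len(k_eff)]
  u <- u[, seq_len(k_eff), drop = FALSE]
  # sign convention: dominant entry of each left singular vector positive
  for (j in seq_len(k_eff)) {
    if (u[which.max(abs(u[, j])), j] < 0) u[, j] <- -u[, j]
  }
  vectors <- u %*% diag(d, nrow = k_eff)
  rownames(vectors) <- ppmi$vocab$concept_id
  colnames(vectors) <- paste0("d", seq_len(k_eff))
  structure(list(vectors = vectors, k = k_eff, singular_values = d,
                 vocab = ppmi$vocab),
            class = "embedding_matrix")
}

#' Write a sparse matrix with its vocabulary sidecar
#'
#' MatrixMarket coordinate text for the matrix plus a TSV sidecar mapping
#' row/column indices to concepts.
#'
#' @param x A `cooccurrence_matrix` or `ppmi_matrix`.
#' @param path Output path for the matrix; the sidecar gets
#'   `<path>.vocab.tsv`.
#' @return `path`, invisibly.
#' @export
write_sparse_matrix <- function(x, path) {
  m <- if (inherits(x, "cooccurrence_matrix")) x$counts
       else if (inherits(x, "ppmi_matrix")) x$values
       else stopf("x must be a cooccurrence_matrix or ppmi_matrix")
  Matrix::writeMM(as(m, "generalMatrix"), path)
  write_vocabulary(x$vocab, paste0(path, ".vocab.tsv"))
  invisible(path)
}

#' Write / read a concept vocabulary as TSV
#'
#' @param vocab A `concept_vocabulary`.
#' @param path TSV path.
#' @return `path` (write) or a tibble (read), invisibly for write.
#' @export
write_vocabulary <- function(vocab, path) {
  utils::write.table(as.data.frame(vocab), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      colClasses = c(index = "integer"),
                                      quote = ""))
}

#' Write concept embeddings as a labelled delimited matrix
#'
#' @param emb An `embedding_matrix`.
#' @param path TSV path; first column `concept_id`, then one column per
#'   dimension.
#' @return `path`, invisibly.
#' @export
write_embedding <- function(emb, path) {
  df <- data.frame(concept_id = rownames(emb$vectors), emb$vectors,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
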