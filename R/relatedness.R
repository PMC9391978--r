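resolve_index <- function(emb, x) {
  if (is.character(x)) {
    idx <- match(x, rownames(emb$vectors))
    if (is.na(idx)) stopf("concept '%s' not in embedding", x)
    idx
  } else {
    x <- as.integer(x)
    if (is.na(x) || x < 1L || x > nrow(emb$vectors)) {
      stopf("index %s out of range 1..%d", format(x), nrow(emb$vectors))
    }
    x
  }
}

#' Cosine relatedness between two concept vectors
#'
#' The normalized dot product \eqn{C_i \cdot C_j / (\|C_i\|\|C_j\|)},
#' clipped to `[-1, 1]` against floating-point rounding. A zero-norm vector
#' is an explicit error naming the concept, never a silent zero.
#'
#' @param emb An `embedding_matrix`.
#' @param i,j Concept ids (character) or vocabulary indices (integer).
#' @return A single numeric in `[-1, 1]`.
#' @export
cosine_relatedness <- function(emb, i, j) {
  ii <- resolve_index(emb, i)
  jj <- resolve_index(emb, j)
  a <- emb$vectors[ii, ]
  b <- emb$vectors[jj, ]
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0) stopf("concept '%s' has a zero-norm vector",
                     rownames(emb$vectors)[ii])
  if (nb == 0) stopf("concept '%s' has a zero-norm vector",
                     rownames(emb$vectors)[jj])
  min(1, max(-1, sum(a * b) / (na * nb)))
}

#' Proportion of condition documents co-mentioning each concept
#'
#' The node "frequency" of the graph schema: for each vocabulary concept,
#' the number of documents containing both the concept and the condition,
#' divided by the number of documents containing the condition (so the
#' condition itself has frequency 1). With
#' `denominator = "all_docs"` the divisor is instead the full filtered
#' corpus size.
#'
#' @param docs Filtered documents.
#' @param vocab A `concept_vocabulary`.
#' @param condition_id Canonical condition concept id.
#' @param denominator `"condition_docs"` (default) or `"all_docs"`.
#' @return Named numeric vector over `vocab$concept_id`, values in `[0, 1]`.
#' @export
condition_frequency <- function(docs, vocab, condition_id,
                                denominator = c("condition_docs", "all_docs")) {
  denominator <- match.arg(denominator)
  cutoff <- attr(vocab, "score_cutoff") %||% 0
  flat <- flatten_mentions(docs)
  flat <- flat[flat$score > cutoff & flat$concept_id %in% vocab$concept_id, ]
  flat <- dplyr::distinct(flat, .data$doc_id, .data$concept_id)
  cond_docs <- unique(flat$doc_id[flat$concept_id == condition_id])
  if (length(cond_docs) == 0L) {
    stopf("condition '%s' appears in no document", condition_id)
  }
  denom <- if (denominator == "condition_docs") length(cond_docs)
           else length(docs)
  in_cond <- flat[flat$doc_id %in% cond_docs, ]
  co <- table(factor(in_cond$concept_id, levels = vocab$concept_id))
  out <- as.numeric(co) / denom
  names(out) <- vocab$concept_id
  out
}

#' Relatedness of every concept to the condition
#'
#' Combines cosine relatedness against the condition vector with the
#' co-mention frequency into one table, one row per vocabulary concept.
#'
#' @param emb An `embedding_matrix`.
#' @param docs The filtered documents (for frequencies).
#' @param condition_id Canonical condition concept id.
#' @param source Corpus tag recorded on the table (defaults to the first
#'   document's source).
#' @param denominator Passed to [condition_frequency()].
#' @return A tibble of class `relatedness_table` with columns `concept_id`,
#'   `name`, `semantic_type`, `relatedness`, `frequency`; attributes
#'   `condition_id` and `source`.
#' @export
relatedness_table <- function(emb, docs, condition_id, source = NULL,
                              denominator = "condition_docs") {
  vocab <- emb$vocab
  if (!condition_id %in% vocab$concept_id) {
    stopf("condition '%s' not in vocabulary", condition_id)
  }
  if (is.null(source)) source <- docs[[1]]$source
  rel <- vapply(vocab$concept_id, function(id) {
    cosine_relatedness(emb, id, condition_id)
  }, numeric(1))
  freq <- condition_frequency(docs, vocab, condition_id,
                              denominator = denominator)
  out <- tibble::tibble(
    concept_id = vocab$concept_id,
    name = vocab$name,
    semantic_type = vocab$semantic_type,
    relatedness = unname(rel),
    frequency = unname(freq[vocab$concept_id])
  )
  structure(out, class = c("relatedness_table", class(tibble::tibble())),
            condition_id = condition_id, source = source)
}

#' Select the top related concepts per semantic type
#'
#' Within each semantic type, concepts are ordered by relatedness to the
#' condition (descending, ties broken by concept id) and at most `top_k`
#' are kept. The condition concept itself is excluded — it is the hub the
#' graph hangs off, never a leaf. Types left with no concepts are omitted.
#'
#' @param table A `relatedness_table`.
#' @param top_k Maximum concepts per type. Default 25.
#' @return A named list of tibbles (one per semantic type, columns
#'   `concept_id`, `name`, `relatedness`, `frequency`, `rank`), class
#'   `ranked_selection`, attributes `condition_id`, `source`, `top_k`.
#' @export
rank_by_semantic_type <- function(table, top_k = 25L) {
  stopifnot(inherits(table, "relatedness_table"))
  if (nrow(table) == 0L) stopf("relatedness table is empty")
  condition_id <- attr(table, "condition_id")
  df <- table[table$concept_id != condition_id, , drop = FALSE]
  df <- tibble::as_tibble(df)
  groups <- split(df, df$semantic_type)
  sel <- lapply(groups, function(g) {
    ord <- order(-g$relatedness, g$concept_id, method = "radix")
    g <- g[ord, c("concept_id", "name", "relatedness", "frequency")]
    g <- head(g, top_k)
    g$rank <- seq_len(nrow(g))
    g
  })
  sel <- sel[vapply(sel, nrow, integer(1)) > 0]
  sel <- sel[order(names(sel), method = "radix")]
  structure(sel, class = "ranked_selection",
            condition_id = condition_id, source = attr(table, "source"),
            top_k = as.integer(top_k))
}

#' Export a relatedness table or ranked selection to TSV
#'
#' @param x A `relatedness_table` or `ranked_selection`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_relatedness <- function(x, path) {
  df <- if (inherits(x, "ranked_selection")) {
    dplyr::bind_rows(lapply(names(x), function(st) {
      cbind(semantic_type = st, as.data.frame(x[[st]]))
    }))
  } else {
    as.data.frame(x)
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
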