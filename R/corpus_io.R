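#' Construct a concept mention
#'
#' A single linker annotation inside a document: a canonical concept
#' identifier (CUI-like), its preferred name, the ordered list of semantic
#' types returned by the linker, and the linker's confidence score.
#'
#' @param concept_id Opaque identifier string.
#' @param name Preferred label.
#' @param semantic_types Character vector of type names, ordered; only the
#'   first is used downstream.
#' @param score Linker confidence in `[0, 1]`.
#' @return A list of class `concept_mention`.
#' @export
concept_mention <- function(concept_id, name, semantic_types, score) {
  if (!is_string(concept_id)) stopf("concept_id must be a single string")
  if (!is.character(semantic_types) || length(semantic_types) < 1L) {
    stopf("mention of '%s': semantic_types must be a non-empty character vector",
          concept_id)
  }
  score <- as.numeric(score)
  if (length(score) != 1L || is.na(score) || score < 0 || score > 1) {
    stopf("mention of '%s': score %s outside [0, 1]", concept_id,
          format(score))
  }
  structure(
    list(concept_id = concept_id, name = as.character(name),
         semantic_types = semantic_types, score = score),
    class = "concept_mention"
  )
}

#' Construct an annotated document
#'
#' @param doc_id Unique document identifier within a corpus.
#' @param source Corpus tag, e.g. `"forum"` or `"pubmed"`.
#' @param mentions List of [concept_mention()] objects (may be empty).
#' @return A list of class `annotated_document`.
#' @export
annotated_document <- function(doc_id, source, mentions = list()) {
  if (!is_string(doc_id)) stopf("doc_id must be a single string")
  if (!is_string(source)) stopf("source must be a single string")
  mentions <- lapply(mentions, function(m) {
    if (inherits(m, "concept_mention")) m
    else concept_mention(m$concept_id, m$name, m$semantic_types, m$score)
  })
  structure(list(doc_id = doc_id, source = source, mentions = mentions),
            class = "annotated_document")
}

#' The default semantic-type allowlist
#'
#' Twenty-six UMLS semantic types curated for neurodevelopmental-disorder
#' corpora (behaviour, findings, procedures, care organisations, ...).
#' Shipped as plain text under `extdata` and overridable in
#' [filter_config()].
#'
#' @return Character vector of 26 type names.
#' @export
default_semantic_types <- function() {
  path <- system.file("extdata", "semantic_types_26.txt",
                      package = "conceptkg", mustWork = TRUE)
  readLines(path, encoding = "UTF-8")
}

#' Filtering configuration for vocabulary construction
#'
#' @param score_cutoff Mentions with linker score at or below this value are
#'   discarded (strictly-greater rule). Default 0.7.
#' @param min_doc_count Concepts must appear in at least this many documents.
#'   Default 10.
#' @param allowed_semantic_types Allowlist applied to each concept's first
#'   semantic type. Default: [default_semantic_types()].
#' @param condition_merge_map Named character vector mapping synonym concept
#'   ids to a canonical condition id (e.g. Asperger syndrome and autistic
#'   disorder both to the ASD concept).
#' @param condition_ids Character vector of canonical condition ids.
#' @param blocklist Concept ids to drop unconditionally (stands in for a
#'   manual false-positive review).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(score_cutoff = 0.7,
                          min_doc_count = 10L,
                          allowed_semantic_types = default_semantic_types(),
                          condition_merge_map = character(),
                          condition_ids = character(),
                          blocklist = character()) {
  if (!is.numeric(score_cutoff) || score_cutoff < 0 || score_cutoff > 1) {
    stopf("score_cutoff must be in [0, 1]")
  }
  min_doc_count <- as.integer(min_doc_count)
  if (is.na(min_doc_count) || min_doc_count < 1L) {
    stopf("min_doc_count must be >= 1")
  }
  if (length(condition_merge_map) &&
      (is.null(names(condition_merge_map)) ||
       any(!nzchar(names(condition_merge_map))))) {
    stopf("condition_merge_map must be a named character vector (from -> to)")
  }
  structure(
    list(score_cutoff = score_cutoff,
         min_doc_count = min_doc_count,
         allowed_semantic_types = as.character(allowed_semantic_types),
         condition_merge_map = condition_merge_map,
         condition_ids = as.character(condition_ids),
         blocklist = as.character(blocklist)),
    class = "filter_config"
  )
}

#' Read a line-delimited annotated corpus
#'
#' One JSON record per line with fields `doc_id`, `source` and `mentions`
#' (each mention: `concept_id`, `name`, `semantic_types`, `score`).
#' Malformed records and invariant violations (duplicate `doc_id`, score
#' outside `[0, 1]`, empty semantic-type list) raise errors naming the
#' offending document rather than being skipped.
#'
#' @param path Path to a UTF-8 JSON-lines file.
#' @return List of [annotated_document()] in file order.
#' @export
read_annotated_corpus <- function(path) {
  if (!file.exists(path)) stopf("corpus file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  docs <- vector("list", length(lines))
  seen <- new.env(parent = emptyenv())
  for (i in seq_along(lines)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[[i]], simplifyVector = FALSE),
      error = function(e) stopf("line %d: not valid JSON (%s)", i,
                                conditionMessage(e))
    )
    if (is.null(rec$doc_id) || is.null(rec$source)) {
      stopf("line %d: record must carry doc_id and source", i)
    }
    doc_id <- as.character(rec$doc_id)
    if (!is.null(seen[[doc_id]])) stopf("duplicate doc_id '%s'", doc_id)
    seen[[doc_id]] <- TRUE
    mentions <- lapply(rec$mentions, function(m) {
      tryCatch(
        concept_mention(as.character(m$concept_id),
                        as.character(m$name %||% m$concept_id),
                        unlist(m$semantic_types, use.names = FALSE),
                        m$score),
        error = function(e) stopf("doc_id '%s': %s", doc_id,
                                  conditionMessage(e))
      )
    })
    docs[[i]] <- annotated_document(doc_id, as.character(rec$source), mentions)
  }
  docs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an annotated corpus to a JSON-lines file
#'
#' Inverse of [read_annotated_corpus()]; deterministic byte-for-byte for a
#' given corpus.
#'
#' @param docs List of [annotated_document()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotated_corpus <- function(docs, path) {
  lines <- vapply(docs, function(d) {
    rec <- list(
      doc_id = d$doc_id, source = d$source,
      mentions = lapply(d$mentions, function(m) {
        list(concept_id = m$concept_id, name = m$name,
             semantic_types = as.list(m$semantic_types), score = m$score)
      })
    )
    as.character(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = 12))
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Keep only documents that mention a target condition
#'
#' Mentions listed in `cfg$condition_merge_map` are first rewritten to their
#' canonical condition id (synonym merging, e.g. Asperger syndrome into ASD);
#' then only documents carrying at least one canonical condition mention are
#' retained. A document mentioning two conditions is kept once and counts for
#' both downstream.
#'
#' @param docs List of [annotated_document()].
#' @param cfg A [filter_config()] with non-empty `condition_ids`.
#' @return Filtered list of documents with merged mentions.
#' @export
filter_condition_documents <- function(docs, cfg) {
  if (length(cfg$condition_ids) == 0L) {
    stopf("filter_config must name at least one condition id")
  }
  merge_map <- cfg$condition_merge_map
  out <- lapply(docs, function(d) {
    if (length(merge_map)) {
      d$mentions <- lapply(d$mentions, function(m) {
        if (m$concept_id %in% names(merge_map)) {
          m$concept_id <- unname(merge_map[[m$concept_id]])
        }
        m
      })
    }
    ids <- vapply(d$mentions, `[[`, character(1), "concept_id")
    if (any(ids %in% cfg$condition_ids)) d else NULL
  })
  out[!vapply(out, is.null, logical(1))]
}

# Flatten a corpus into one row per (document, mention).
flatten_mentions <- function(docs) {
  rows <- lapply(docs, function(d) {
    if (length(d$mentions) == 0L) return(NULL)
    tibble::tibble(
      doc_id = d$doc_id,
      concept_id = vapply(d$mentions, `[[`, character(1), "concept_id"),
      name = vapply(d$mentions, `[[`, character(1), "name"),
      semantic_type = vapply(d$mentions, function(m) m$semantic_types[[1]],
                             character(1)),
      score = vapply(d$mentions, `[[`, numeric(1), "score")
    )
  })
  dplyr::bind_rows(rows)
}

#' Build the concept vocabulary for one source
#'
#' Applies the mention-level and concept-level filters in order: linker
#' scores must exceed `score_cutoff` (strict); each concept is typed by the
#' FIRST semantic type in its list; the type must sit in the allowlist; the
#' concept must not be blocklisted; and the concept must appear in at least
#' `min_doc_count` distinct documents (multiple mentions in one document
#' count once). Condition concepts bypass the type and count filters so the
#' graph's anchor always exists. Indices are assigned by descending document
#' count with ties broken by concept id, so the vocabulary is reproducible.
#'
#' @param docs Filtered documents (see [filter_condition_documents()]).
#' @param cfg A [filter_config()].
#' @return A tibble of class `concept_vocabulary` with columns `concept_id`,
#'   `name`, `semantic_type`, `index` (1..n, dense), `doc_count`,
#'   `is_condition`, and attributes `n` and `n_docs`.
#' @export
build_vocabulary <- function(docs, cfg) {
  if (length(docs) == 0L) stopf("cannot build a vocabulary from zero documents")
  flat <- flatten_mentions(docs)
  if (nrow(flat) == 0L) stopf("corpus has no mentions")
  flat <- dplyr::filter(flat, .data$score > cfg$score_cutoff)
  # one row per (doc, concept); first-seen name/type is the concept's
  flat <- dplyr::distinct(flat, .data$doc_id, .data$concept_id,
                          .keep_all = TRUE)
  counts <- flat |>
    dplyr::group_by(.data$concept_id) |>
    dplyr::summarise(name = dplyr::first(.data$name),
                     semantic_type = dplyr::first(.data$semantic_type),
                     doc_count = dplyr::n_distinct(.data$doc_id),
                     .groups = "drop")
  counts$is_condition <- counts$concept_id %in% cfg$condition_ids
  missing_cond <- setdiff(cfg$condition_ids, counts$concept_id)
  if (length(missing_cond)) {
    stopf("condition concept(s) absent from all documents after score filter: %s",
          paste(missing_cond, collapse = ", "))
  }
  keep <- counts$is_condition |
    (counts$semantic_type %in% cfg$allowed_semantic_types &
       !(counts$concept_id %in% cfg$blocklist) &
       counts$doc_count >= cfg$min_doc_count)
  vocab <- counts[keep, , drop = FALSE]
  if (nrow(vocab) == 0L) {
    stopf("vocabulary is empty after filtering; lower score_cutoff or min_doc_count")
  }
  ord <- order(-vocab$doc_count, vocab$concept_id, method = "radix")
  vocab <- vocab[ord, , drop = FALSE]
  vocab$index <- seq_len(nrow(vocab))
  vocab <- vocab[, c("concept_id", "name", "semantic_type", "index",
                     "doc_count", "is_condition")]
  structure(vocab, class = c("concept_vocabulary", class(tibble::tibble())),
            n = nrow(vocab), n_docs = length(docs),
            score_cutoff = cfg$score_cutoff)
}

#' Restrict a corpus to a vocabulary's surviving mentions
#'
#' Keeps, in each document, only mentions whose concept survives in `vocab`
#' and whose score passes the cutoff. Re-running [build_vocabulary()] on the
#' pruned corpus reproduces `vocab` (the filters are idempotent).
#'
#' @param docs List of [annotated_document()].
#' @param vocab A `concept_vocabulary`.
#' @param cfg The [filter_config()] used to build `vocab`.
#' @return Pruned list of documents.
#' @export
prune_to_vocabulary <- function(docs, vocab, cfg) {
  keep_ids <- vocab$concept_id
  lapply(docs, function(d) {
    d$mentions <- Filter(function(m) {
      m$concept_id %in% keep_ids && m$score > cfg$score_cutoff
    }, d$mentions)
    d
  })
}

#' @export
print.concept_vocabulary <- function(x, ...) {
  cat(sprintf("<concept_vocabulary> %d concepts over %d documents\n",
              attr(x, "n"), attr(x, "n_docs")))
  NextMethod()
}
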