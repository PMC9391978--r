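#' Specification for a synthetic annotated corpus
#'
#' Describes a corpus generator with planted topic structure: every document
#' draws one latent topic; members of the drawn topic are emitted
#' independently with their in-topic probabilities, members of all other
#' topics leak in at a small cross-topic rate, and background concepts are
#' emitted in every document regardless of topic. The target condition is an
#' ordinary member of one topic, so the concepts sharing its topic are the
#' ground-truth "related" set and every downstream ranking has a known
#' answer.
#'
#' The defaults encode the reference study conditions used throughout the
#' package's validation: 1000 documents, two topics of eight concepts each,
#' in-topic emission 0.8 and cross-topic leak 0.02. Each topic is anchored
#' by its own condition concept (emulating a corpus about two conditions,
#' e.g. ASD and ADHD). Two anchors matter: the document filter keeps only
#' condition-mentioning documents, so with a single condition the target
#' would co-occur with everything at probability one and carry no
#' co-occurrence information at all.
#'
#' @param n_docs Number of documents. Default 1000.
#' @param topics Named list: `topic_id -> character vector of member concept
#'   ids`. The condition id must be a member of `condition_topic`.
#' @param emission In-topic emission probability, scalar or named per-concept
#'   vector. Default 0.8.
#' @param out_topic_emission Probability that a topic member appears in a
#'   document whose drawn topic is a different one. Default 0.02.
#' @param condition_id Concept id of the target condition. Default
#'   `"C0000"`.
#' @param condition_ids All condition anchor ids (the target plus the other
#'   topics' anchors). Default: `condition_id` plus `"C0001"` anchoring the
#'   second default topic.
#' @param condition_topic Topic the condition belongs to. Default first topic.
#' @param background Named numeric vector `concept_id -> emission
#'   probability`, applied in every document regardless of topic. Default:
#'   none. Note that heavily emitted background concepts are adversarial
#'   for PPMI embeddings: clamping negative PMI at zero biases all vectors
#'   into the positive orthant, so a concept present everywhere can acquire
#'   a spuriously high cosine to the condition.
#' @param semantic_type_map Named list `concept_id -> ordered character
#'   vector of semantic types`. Concepts without an entry default to
#'   `"finding"`; the condition defaults to
#'   `"mental or behavioral dysfunction"`.
#' @param name_map Named character vector `concept_id -> display name`;
#'   missing entries fall back to the id.
#' @param score_range Length-2 numeric, uniform sampling bounds for linker
#'   scores. Default `c(0.75, 1)` (all pass the 0.7 cutoff).
#' @param decoy_rate Fraction of mentions whose score is instead drawn from
#'   `decoy_score_range`, to exercise the score cutoff. Default 0.
#' @param decoy_score_range Bounds for decoy scores. Default `c(0.2, 0.6)`.
#' @param topic_weights Sampling weights over topics (uniform by default).
#' @param source Corpus tag stamped on every document. Default
#'   `"synthetic"`.
#' @param seed Integer seed making generation a pure function of the spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_docs = 1000L,
                           topics = NULL,
                           emission = 0.8,
                           out_topic_emission = 0.02,
                           condition_id = "C0000",
                           condition_ids = NULL,
                           condition_topic = NULL,
                           background = setNames(numeric(0), character(0)),
                           semantic_type_map = list(),
                           name_map = character(),
                           score_range = c(0.75, 1),
                           decoy_rate = 0,
                           decoy_score_range = c(0.2, 0.6),
                           topic_weights = NULL,
                           source = "synthetic",
                           seed = 1L) {
  if (is.null(topics)) {
    topics <- list(
      t1 = c(condition_id, sprintf("C01%02d", 1:8)),
      t2 = c("C0001", sprintf("C02%02d", 1:8))
    )
    if (is.null(condition_ids)) condition_ids <- c(condition_id, "C0001")
  }
  if (is.null(condition_ids)) condition_ids <- condition_id
  if (!condition_id %in% condition_ids) {
    stopf("condition_id must be among condition_ids")
  }
  if (is.null(condition_topic)) {
    hit <- vapply(topics, function(m) condition_id %in% m, logical(1))
    if (!any(hit)) stopf("condition '%s' belongs to no topic", condition_id)
    condition_topic <- names(topics)[which(hit)[1]]
  }
  n_docs <- as.integer(n_docs)
  if (is.na(n_docs) || n_docs < 1L) stopf("n_docs must be >= 1")
  if (!condition_topic %in% names(topics)) {
    stopf("unknown condition_topic '%s'", condition_topic)
  }
  if (!condition_id %in% topics[[condition_topic]]) {
    stopf("condition '%s' is not a member of topic '%s'", condition_id,
          condition_topic)
  }
  all_members <- unlist(topics, use.names = FALSE)
  if (anyDuplicated(all_members)) stopf("topic member sets must be disjoint")
  if (length(intersect(all_members, names(background)))) {
    stopf("background concepts must be disjoint from topic members")
  }
  probs <- c(emission, out_topic_emission, background, decoy_rate)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (is.null(topic_weights)) {
    topic_weights <- rep(1 / length(topics), length(topics))
  }
  structure(
    list(n_docs = n_docs, topics = topics, emission = emission,
         out_topic_emission = out_topic_emission,
         condition_id = condition_id, condition_ids = condition_ids,
         condition_topic = condition_topic,
         background = background, semantic_type_map = semantic_type_map,
         name_map = name_map, score_range = as.numeric(score_range),
         decoy_rate = decoy_rate,
         decoy_score_range = as.numeric(decoy_score_range),
         topic_weights = topic_weights, source = source,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

concept_types <- function(spec, id) {
  st <- spec$semantic_type_map[[id]]
  if (!is.null(st)) return(as.character(st))
  if (id %in% spec$condition_ids) "mental or behavioral dysfunction"
  else "finding"
}

concept_name <- function(spec, id) {
  nm <- spec$name_map[id]
  if (is.na(nm)) id else unname(nm)
}

#' Generate a synthetic annotated corpus with known ground truth
#'
#' @param spec A [synthetic_spec()].
#' @param seed Overrides `spec$seed` when given.
#' @return List with `docs` (list of [annotated_document()]) and
#'   `ground_truth` (list with `in_topic_concepts`, the concepts sharing the
#'   condition's topic, and `out_topic_concepts`, every other non-condition
#'   concept).
#' @export
generate_corpus <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "synthetic_spec"))
  emissions <- function(members) {
    e <- spec$emission
    if (is.null(names(e))) rep_len(e, length(members))
    else {
      v <- e[members]
      if (anyNA(v)) stopf("per-concept emission missing for: %s",
                          paste(members[is.na(v)], collapse = ", "))
      unname(v)
    }
  }
  docs <- with_local_seed(seed, {
    topic_ids <- names(spec$topics)
    lapply(seq_len(spec$n_docs), function(d) {
      drawn <- sample(topic_ids, 1L, prob = spec$topic_weights)
      present <- character(0)
      for (t in topic_ids) {
        members <- spec$topics[[t]]
        p <- if (t == drawn) emissions(members)
             else rep_len(spec$out_topic_emission, length(members))
        present <- c(present, members[runif(length(members)) < p])
      }
      bg <- names(spec$background)
      present <- c(present, bg[runif(length(bg)) < spec$background])
      mentions <- lapply(present, function(id) {
        decoy <- spec$decoy_rate > 0 && runif(1) < spec$decoy_rate
        rng <- if (decoy) spec$decoy_score_range else spec$score_range
        concept_mention(id, concept_name(spec, id), concept_types(spec, id),
                        runif(1, rng[1], rng[2]))
      })
      annotated_document(sprintf("%s-%06d", spec$source, d), spec$source,
                         mentions)
    })
  })
  in_topic <- setdiff(spec$topics[[spec$condition_topic]], spec$condition_ids)
  out_topic <- setdiff(
    c(unlist(spec$topics, use.names = FALSE), names(spec$background)),
    c(in_topic, spec$condition_ids)
  )
  list(docs = docs,
       ground_truth = list(in_topic_concepts = in_topic,
                           out_topic_concepts = out_topic))
}

#' Annotate raw text with a fixed dictionary
#'
#' A deliberately simple stand-in for a biomedical entity linker, useful for
#' building small fixtures: case-insensitive, longest-match exact matching
#' over whitespace tokens. Matched spans become mentions with score 1.0;
#' unmatched text is ignored.
#'
#' @param texts Data frame (or tibble) with columns `doc_id` and `text`.
#' @param lexicon Named list: lowercase surface string -> list with
#'   `concept_id`, `semantic_types`, and optional `name`.
#' @param source Corpus tag for the produced documents.
#' @return List of [annotated_document()].
#' @export
annotate_with_dictionary <- function(texts, lexicon, source = "dictionary") {
  if (length(lexicon) == 0L) stopf("lexicon must be non-empty")
  names(lexicon) <- tolower(names(lexicon))
  max_len <- max(lengths(strsplit(names(lexicon), "\\s+")))
  lapply(seq_len(nrow(texts)), function(i) {
    toks <- strsplit(tolower(trimws(texts$text[[i]])), "\\s+")[[1]]
    toks <- toks[nzchar(toks)]
    mentions <- list()
    pos <- 1L
    while (pos <= length(toks)) {
      hit <- NULL
      for (len in seq(min(max_len, length(toks) - pos + 1L), 1L)) {
        key <- paste(toks[pos:(pos + len - 1L)], collapse = " ")
        if (!is.null(lexicon[[key]])) {
          hit <- lexicon[[key]]
          pos <- pos + len
          break
        }
      }
      if (is.null(hit)) pos <- pos + 1L
      else {
        mentions[[length(mentions) + 1L]] <- concept_mention(
          hit$concept_id, hit$name %||% hit$concept_id,
          as.character(hit$semantic_types), 1.0)
      }
    }
    annotated_document(as.character(texts$doc_id[[i]]), source, mentions)
  })
}
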