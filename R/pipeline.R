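#' Configuration for the end-to-end pipeline
#'
#' Centralizes every tunable of the pipeline with the reference defaults:
#' linker-score cutoff 0.7, minimum document count 10, the 26-type semantic
#' allowlist, embedding dimension `k = 300`, top 25 concepts per semantic
#' type, and the 2-standard-deviation comparison band.
#'
#' @param corpus_paths Character vector of one or two annotated-corpus
#'   files (two are required for [run_comparison()]).
#' @param condition_id Canonical condition concept id (the graph's anchor).
#' @param filter A [filter_config()]; defaults to one anchored on
#'   `condition_id`.
#' @param k Embedding dimension. Default 300.
#' @param top_k Concepts kept per semantic type. Default 25.
#' @param frequency_denominator `"condition_docs"` or `"all_docs"`, see
#'   [condition_frequency()].
#' @param keep_diagonal Passed to [compute_ppmi()]. Default `FALSE`.
#' @param exact_limit Passed to [embed_svd()]. Default 2000.
#' @param restrict_comparison Restrict the two-corpus comparison to the
#'   union of both top-k selections (default `TRUE`).
#' @param source_tags Optional character vector (one per corpus) overriding
#'   the source tag carried by the documents; needed e.g. to compare a
#'   corpus against itself under two labels.
#' @param seed Integer seed for all randomized stages.
#' @param out_dir Run directory for artifacts and manifests.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(corpus_paths,
                            condition_id,
                            filter = NULL,
                            k = 300L,
                            top_k = 25L,
                            frequency_denominator = "condition_docs",
                            keep_diagonal = FALSE,
                            exact_limit = 2000L,
                            restrict_comparison = TRUE,
                            source_tags = NULL,
                            seed = 1L,
                            out_dir = tempfile("conceptkg-run-")) {
  if (length(corpus_paths) < 1L || length(corpus_paths) > 2L) {
    stopf("corpus_paths must name one or two corpora")
  }
  if (!is.null(source_tags) && length(source_tags) != length(corpus_paths)) {
    stopf("source_tags must match corpus_paths in length")
  }
  if (is.null(filter)) filter <- filter_config(condition_ids = condition_id)
  if (!condition_id %in% filter$condition_ids) {
    stopf("condition_id '%s' missing from filter$condition_ids", condition_id)
  }
  structure(
    list(corpus_paths = as.character(corpus_paths),
         condition_id = condition_id, filter = filter,
         k = as.integer(k), top_k = as.integer(top_k),
         frequency_denominator = frequency_denominator,
         keep_diagonal = keep_diagonal,
         exact_limit = as.integer(exact_limit),
         restrict_comparison = isTRUE(restrict_comparison),
         source_tags = source_tags,
         seed = as.integer(seed), out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Load a pipeline configuration from YAML
#'
#' Accepts the same fields as [pipeline_config()]; `filter` may be a nested
#' mapping with [filter_config()] fields.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  filt <- NULL
  if (!is.null(y$filter)) {
    fargs <- y$filter
    if (!is.null(fargs$condition_merge_map)) {
      fargs$condition_merge_map <- unlist(fargs$condition_merge_map)
    }
    if (is.null(fargs$condition_ids)) fargs$condition_ids <- y$condition_id
    filt <- do.call(filter_config, fargs)
  }
  args <- y[setdiff(names(y), "filter")]
  args$filter <- filt
  do.call(pipeline_config, args)
}

config_fingerprint <- function(cfg) {
  md5_string(canonical_json(list(
    corpus_paths = basename(cfg$corpus_paths),
    condition_id = cfg$condition_id,
    filter = unclass(cfg$filter),
    k = cfg$k, top_k = cfg$top_k,
    frequency_denominator = cfg$frequency_denominator,
    keep_diagonal = cfg$keep_diagonal,
    exact_limit = cfg$exact_limit,
    restrict_comparison = cfg$restrict_comparison,
    source_tags = cfg$source_tags,
    seed = cfg$seed
  )))
}

run_stage <- function(stage, expr) {
  tryCatch(force(expr), error = function(e) {
    stopf("pipeline stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

#' Run the single-source pipeline
#'
#' Executes corpus reading, condition filtering, vocabulary construction,
#' co-occurrence counting, PPMI, truncated SVD, relatedness ranking and
#' knowledge-graph construction for one corpus, writing every intermediate
#' artifact plus a manifest (config hash, seed, effective dimension, and
#' the document/concept counts at each filter stage) under
#' `out_dir/<source>/`. Any stage failure aborts with the stage name and
#' cause. Identical config and seed produce byte-identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @param corpus Optional pre-read list of [annotated_document()]; when
#'   `NULL`, `cfg$corpus_paths[[which]]` is read.
#' @param which Index of the corpus path to run (1 or 2).
#' @return List with `vocab`, `embedding`, `relatedness`, `selection`,
#'   `kg`, `manifest`, `out_dir` (the per-source directory).
#' @export
run_single_source <- function(cfg, corpus = NULL, which = 1L) {
  stopifnot(inherits(cfg, "pipeline_config"))
  docs <- run_stage("read_annotated_corpus", {
    if (is.null(corpus)) read_annotated_corpus(cfg$corpus_paths[[which]])
    else corpus
  })
  if (length(docs) == 0L) stopf("pipeline stage 'read_annotated_corpus' failed: empty corpus")
  if (!is.null(cfg$source_tags)) {
    tag <- cfg$source_tags[[which]]
    docs <- lapply(docs, function(d) { d$source <- tag; d })
  }
  source <- docs[[1]]$source
  filtered <- run_stage("filter_condition_documents",
                        filter_condition_documents(docs, cfg$filter))
  vocab <- run_stage("build_vocabulary", build_vocabulary(filtered, cfg$filter))
  cooc <- run_stage("build_cooccurrence", build_cooccurrence(filtered, vocab))
  ppmi <- run_stage("compute_ppmi",
                    compute_ppmi(cooc, keep_diagonal = cfg$keep_diagonal))
  emb <- run_stage("embed_svd",
                   embed_svd(ppmi, k = cfg$k, exact_limit = cfg$exact_limit,
                             seed = cfg$seed))
  rel <- run_stage("relatedness_table",
                   relatedness_table(emb, filtered, cfg$condition_id,
                                     source = source,
                                     denominator = cfg$frequency_denominator))
  sel <- run_stage("rank_by_semantic_type",
                   rank_by_semantic_type(rel, top_k = cfg$top_k))
  kg <- run_stage("build_kg", build_kg(sel))
  dir <- file.path(cfg$out_dir, source)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  run_stage("export", {
    write_vocabulary(vocab, file.path(dir, "vocabulary.tsv"))
    write_sparse_matrix(cooc, file.path(dir, "cooccurrence.mtx"))
    write_sparse_matrix(ppmi, file.path(dir, "ppmi.mtx"))
    write_embedding(emb, file.path(dir, "embedding.tsv"))
    write_relatedness(rel, file.path(dir, "relatedness.tsv"))
    write_relatedness(sel, file.path(dir, "selection.tsv"))
    export_graph(kg, file.path(dir, "kg.graphml"), format = "graphml")
    export_graph(kg, file.path(dir, "kg"), format = "csv_pair")
  })
  manifest <- list(
    config_hash = config_fingerprint(cfg),
    seed = cfg$seed,
    source = source,
    condition_id = cfg$condition_id,
    n_docs_in = length(docs),
    n_docs_condition = length(filtered),
    vocab_size = nrow(vocab),
    requested_k = cfg$k,
    effective_k = emb$k,
    n_semantic_types = length(sel),
    n_selected_concepts = sum(vapply(sel, nrow, integer(1)))
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(vocab = vocab, embedding = emb, relatedness = rel, selection = sel,
       kg = kg, manifest = manifest, out_dir = dir)
}

#' Run the two-corpus comparison pipeline
#'
#' Runs [run_single_source()] on both configured corpora with the shared
#' condition settings, links the two graphs with `sameAs` edges, computes
#' per-concept score differences and classifies each shared concept as of
#' similar, first-source or second-source priority. All outputs (both
#' single-source runs, the merged graph, the classified table and a
#' comparison manifest) are written under `cfg$out_dir`.
#'
#' @param cfg A [pipeline_config()] with two corpus paths.
#' @param corpora Optional list of two pre-read corpora.
#' @return List with `run_a`, `run_b`, `merged_kg`, `comparison`,
#'   `manifest`.
#' @export
run_comparison <- function(cfg, corpora = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (length(cfg$corpus_paths) != 2L && is.null(corpora)) {
    stopf("comparison requires two corpora")
  }
  run_a <- run_single_source(cfg, corpus = if (is.null(corpora)) NULL else corpora[[1]],
                             which = 1L)
  run_b <- run_single_source(cfg, corpus = if (is.null(corpora)) NULL else corpora[[2]],
                             which = 2L)
  merged <- run_stage("link_same_as", link_same_as(run_a$kg, run_b$kg))
  restrict <- NULL
  if (cfg$restrict_comparison) {
    restrict <- union(
      unlist(lapply(run_a$selection, `[[`, "concept_id"), use.names = FALSE),
      unlist(lapply(run_b$selection, `[[`, "concept_id"), use.names = FALSE)
    )
  }
  comp <- run_stage("score_differences",
                    score_differences(run_a$relatedness, run_b$relatedness,
                                      restrict_to = restrict))
  comp <- run_stage("classify_concepts", classify_concepts(comp))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  run_stage("export", {
    export_graph(merged, file.path(cfg$out_dir, "kg_merged.graphml"),
                 format = "graphml")
    export_graph(merged, file.path(cfg$out_dir, "kg_merged"),
                 format = "csv_pair")
    write_comparison(comp, file.path(cfg$out_dir, "comparison.tsv"))
  })
  counts <- table(factor(comp$category,
                         levels = c("similar", "forum_priority",
                                    "pubmed_priority")))
  manifest <- list(
    config_hash = config_fingerprint(cfg),
    seed = cfg$seed,
    sources = c(run_a$manifest$source, run_b$manifest$source),
    condition_id = cfg$condition_id,
    sameas_count = merged$sameas_count,
    n_compared = nrow(comp),
    mu = attr(comp, "mu"),
    sigma = attr(comp, "sigma"),
    n_similar = as.integer(counts[["similar"]]),
    n_forum_priority = as.integer(counts[["forum_priority"]]),
    n_pubmed_priority = as.integer(counts[["pubmed_priority"]])
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "comparison_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  list(run_a = run_a, run_b = run_b, merged_kg = merged, comparison = comp,
       manifest = manifest)
}
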