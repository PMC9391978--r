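node_id_for <- function(source, kind, ref) {
  if (kind == "semantic_type") paste(source, "st", ref, sep = ":")
  else paste(source, ref, sep = ":")
}

#' Materialize a knowledge graph from a ranked selection
#'
#' Builds the typed property graph: one condition node (frequency 1), one
#' node per semantic type whose frequency is the arithmetic mean of its
#' selected concepts' frequencies, and one node per selected concept. Each
#' concept carries an `isA` edge to its semantic type, weighted by its
#' relatedness to the condition; each semantic type carries one unweighted
#' `isRelatedTo` edge to the condition. Node ids are namespaced by source so
#' the same concept can exist on both sides of a merged graph.
#'
#' @param sel A `ranked_selection` from [rank_by_semantic_type()].
#' @param condition_id Canonical condition concept id (defaults to the
#'   selection's).
#' @param source Corpus tag (defaults to the selection's).
#' @param condition_label Display label for the condition node.
#' @return A list of class `knowledge_graph` with tibbles `nodes`
#'   (`node_id`, `kind`, `label`, `frequency`, `source`, `ref`) and `edges`
#'   (`edge_id`, `from`, `to`, `relation`, `weight`; weight is `NA` except
#'   on `isA`), plus `condition_id`, `source`, `top_k`.
#' @export
build_kg <- function(sel, condition_id = attr(sel, "condition_id"),
                     source = attr(sel, "source"),
                     condition_label = condition_id) {
  stopifnot(inherits(sel, "ranked_selection"))
  if (length(sel) == 0L) stopf("ranked selection is empty")
  cond_node <- tibble::tibble(
    node_id = node_id_for(source, "condition", condition_id),
    kind = "condition", label = condition_label, frequency = 1,
    source = source, ref = condition_id
  )
  type_nodes <- dplyr::bind_rows(lapply(names(sel), function(st) {
    tibble::tibble(
      node_id = node_id_for(source, "semantic_type", st),
      kind = "semantic_type", label = st,
      frequency = mean(sel[[st]]$frequency),
      source = source, ref = st
    )
  }))
  concept_nodes <- dplyr::bind_rows(lapply(names(sel), function(st) {
    g <- sel[[st]]
    tibble::tibble(
      node_id = node_id_for(source, "concept", g$concept_id),
      kind = "concept", label = g$name, frequency = g$frequency,
      source = source, ref = g$concept_id
    )
  }))
  isa_edges <- dplyr::bind_rows(lapply(names(sel), function(st) {
    g <- sel[[st]]
    tibble::tibble(
      from = node_id_for(source, "concept", g$concept_id),
      to = node_id_for(source, "semantic_type", st),
      relation = "isA", weight = g$relatedness
    )
  }))
  rel_edges <- tibble::tibble(
    from = node_id_for(source, "semantic_type", names(sel)),
    to = cond_node$node_id,
    relation = "isRelatedTo", weight = NA_real_
  )
  edges <- dplyr::bind_rows(isa_edges, rel_edges)
  edges$edge_id <- paste(edges$relation, edges$from, edges$to, sep = "|")
  edges <- edges[, c("edge_id", "from", "to", "relation", "weight")]
  structure(
    list(nodes = dplyr::bind_rows(cond_node, type_nodes, concept_nodes),
         edges = edges, condition_id = condition_id, source = source,
         top_k = attr(sel, "top_k")),
    class = "knowledge_graph"
  )
}

#' Validate the knowledge-graph schema invariants
#'
#' Checks every structural rule of the graph schema: frequencies in
#' `[0, 1]`; unique `(kind, label, source)` triples; exactly one `isA` per
#' concept node, pointing to a semantic-type node of the same source;
#' exactly one `isRelatedTo` per semantic-type node, pointing to its
#' source's condition node; weights present on `isA` edges only; at most
#' `top_k` concepts per semantic type; and `sameAs` edges only between
#' concept nodes of different sources, at most one per concept id.
#'
#' @param kg A `knowledge_graph`.
#' @return `TRUE` invisibly; raises an error describing the first violated
#'   invariant otherwise.
#' @export
validate_kg <- function(kg) {
  stopifnot(inherits(kg, "knowledge_graph"))
  n <- kg$nodes; e <- kg$edges
  if (any(is.na(n$frequency) | n$frequency < 0 | n$frequency > 1)) {
    stopf("node frequency outside [0, 1]")
  }
  if (anyDuplicated(n[, c("kind", "label", "source")])) {
    stopf("duplicate (kind, label, source) node")
  }
  if (!all(e$from %in% n$node_id) || !all(e$to %in% n$node_id)) {
    stopf("edge endpoint references a missing node")
  }
  if (!all(e$relation %in% c("isA", "isRelatedTo", "sameAs"))) {
    stopf("unknown edge relation")
  }
  if (any(e$relation == "isA" & is.na(e$weight)) ||
      any(e$relation != "isA" & !is.na(e$weight))) {
    stopf("weights must be present on isA edges and absent elsewhere")
  }
  kind_of <- setNames(n$kind, n$node_id)
  src_of <- setNames(n$source, n$node_id)
  isa <- e[e$relation == "isA", ]
  if (!all(kind_of[isa$from] == "concept" &
           kind_of[isa$to] == "semantic_type" &
           src_of[isa$from] == src_of[isa$to])) {
    stopf("isA edges must run concept -> semantic_type within one source")
  }
  concepts <- n$node_id[n$kind == "concept"]
  isa_count <- table(factor(isa$from, levels = concepts))
  if (any(isa_count != 1L)) {
    stopf("concept node(s) without exactly one isA edge: %s",
          paste(names(isa_count)[isa_count != 1L], collapse = ", "))
  }
  rel <- e[e$relation == "isRelatedTo", ]
  if (!all(kind_of[rel$from] == "semantic_type" &
           kind_of[rel$to] == "condition" &
           src_of[rel$from] == src_of[rel$to])) {
    stopf("isRelatedTo edges must run semantic_type -> condition within one source")
  }
  types <- n$node_id[n$kind == "semantic_type"]
  rel_count <- table(factor(rel$from, levels = types))
  if (any(rel_count != 1L)) {
    stopf("semantic-type node(s) without exactly one isRelatedTo edge")
  }
  if (!is.null(kg$top_k) && !is.na(kg$top_k)) {
    per_type <- table(isa$to)
    if (any(per_type > kg$top_k)) {
      stopf("semantic type with more than top_k = %d concepts", kg$top_k)
    }
  }
  same <- e[e$relation == "sameAs", ]
  if (nrow(same)) {
    ref_of <- setNames(n$ref, n$node_id)
    ok <- kind_of[same$from] == "concept" & kind_of[same$to] == "concept" &
      src_of[same$from] != src_of[same$to] &
      ref_of[same$from] == ref_of[same$to]
    if (!all(ok)) {
      stopf("sameAs edges must join the same concept across different sources")
    }
    if (anyDuplicated(ref_of[same$from])) {
      stopf("more than one sameAs edge for one concept id")
    }
  }
  invisible(TRUE)
}

#' Link two single-source graphs with sameAs edges
#'
#' Merges the nodes and edges of two knowledge graphs built from different
#' sources and adds exactly one `sameAs` edge (undirected semantics, no
#' weight) for every concept id that appears as a concept node in BOTH
#' graphs — the concepts of shared concern between the two stakeholder
#' corpora.
#'
#' @param kg_a,kg_b `knowledge_graph` objects with distinct `source` tags.
#' @return A merged `knowledge_graph`; its `source` is
#'   `"<a>+<b>"` and `sameas_count` records the overlap size.
#' @export
link_same_as <- function(kg_a, kg_b) {
  stopifnot(inherits(kg_a, "knowledge_graph"),
            inherits(kg_b, "knowledge_graph"))
  if (identical(kg_a$source, kg_b$source)) {
    stopf("cannot link two graphs with the same source '%s'", kg_a$source)
  }
  ca <- kg_a$nodes[kg_a$nodes$kind == "concept", ]
  cb <- kg_b$nodes[kg_b$nodes$kind == "concept", ]
  shared <- sort(intersect(ca$ref, cb$ref), method = "radix")
  same <- tibble::tibble(
    from = ca$node_id[match(shared, ca$ref)],
    to = cb$node_id[match(shared, cb$ref)],
    relation = "sameAs", weight = NA_real_
  )
  same$edge_id <- paste(same$relation, same$from, same$to, sep = "|")
  same <- same[, c("edge_id", "from", "to", "relation", "weight")]
  structure(
    list(nodes = dplyr::bind_rows(kg_a$nodes, kg_b$nodes),
         edges = dplyr::bind_rows(kg_a$edges, kg_b$edges, same),
         condition_id = kg_a$condition_id,
         source = paste(kg_a$source, kg_b$source, sep = "+"),
         top_k = kg_a$top_k, sameas_count = length(shared)),
    class = "knowledge_graph"
  )
}

#' Export a knowledge graph to GraphML or a CSV node/edge pair
#'
#' GraphML carries node attributes `kind`, `label`, `frequency`, `source`
#' and edge attributes `relation`, `weight`; unweighted edges omit the
#' weight attribute entirely rather than writing 0. The CSV pair
#' (`<path>_nodes.csv`, `<path>_edges.csv`) uses headers
#' `node_id,kind,label,frequency,source` and `from,to,relation,weight`
#' (empty weight field for unweighted edges), loadable by common
#' graph-database bulk importers. [read_graph_file()] reverses either
#' format exactly.
#'
#' @param kg A `knowledge_graph`.
#' @param path Output path (GraphML file, or prefix for the CSV pair).
#' @param format `"graphml"` or `"csv_pair"`.
#' @return The written file path(s), invisibly.
#' @export
export_graph <- function(kg, path, format = c("graphml", "csv_pair")) {
  format <- match.arg(format)
  validate_kg(kg)
  if (format == "graphml") {
    export_graphml(kg, path)
    invisible(path)
  } else {
    np <- paste0(path, "_nodes.csv"); ep <- paste0(path, "_edges.csv")
    nodes <- kg$nodes[, c("node_id", "kind", "label", "frequency", "source")]
    utils::write.csv(nodes, np, row.names = FALSE, quote = TRUE, na = "")
    edges <- kg$edges[, c("from", "to", "relation", "weight")]
    utils::write.csv(edges, ep, row.names = FALSE, quote = TRUE, na = "")
    invisible(c(np, ep))
  }
}

export_graphml <- function(kg, path) {
  doc <- xml2::xml_new_root(
    "graphml",
    xmlns = "http://graphml.graphdrawing.org/xmlns"
  )
  keys <- list(
    c(id = "kind", `for` = "node", attr.name = "kind", attr.type = "string"),
    c(id = "label", `for` = "node", attr.name = "label", attr.type = "string"),
    c(id = "frequency", `for` = "node", attr.name = "frequency",
      attr.type = "double"),
    c(id = "nsource", `for` = "node", attr.name = "source",
      attr.type = "string"),
    c(id = "relation", `for` = "edge", attr.name = "relation",
      attr.type = "string"),
    c(id = "weight", `for` = "edge", attr.name = "weight",
      attr.type = "double")
  )
  for (k in keys) do.call(xml2::xml_add_child, c(list(doc, "key"), as.list(k)))
  graph <- xml2::xml_add_child(doc, "graph", id = kg$source,
                               edgedefault = "directed")
  add_data <- function(parent, key, value) {
    d <- xml2::xml_add_child(parent, "data", key = key)
    xml2::xml_set_text(d, as.character(value))
  }
  for (i in seq_len(nrow(kg$nodes))) {
    nd <- xml2::xml_add_child(graph, "node", id = kg$nodes$node_id[i])
    add_data(nd, "kind", kg$nodes$kind[i])
    add_data(nd, "label", kg$nodes$label[i])
    add_data(nd, "frequency", format(kg$nodes$frequency[i], digits = 15))
    add_data(nd, "nsource", kg$nodes$source[i])
  }
  for (i in seq_len(nrow(kg$edges))) {
    ed <- xml2::xml_add_child(graph, "edge", id = kg$edges$edge_id[i],
                              source = kg$edges$from[i],
                              target = kg$edges$to[i])
    add_data(ed, "relation", kg$edges$relation[i])
    if (!is.na(kg$edges$weight[i])) {
      add_data(ed, "weight", format(kg$edges$weight[i], digits = 15))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

ref_from_node_id <- function(node_id, kind, source) {
  prefix <- ifelse(kind == "semantic_type", paste0(source, ":st:"),
                   paste0(source, ":"))
  substring(node_id, nchar(prefix) + 1L)
}

#' Read a knowledge graph written by [export_graph()]
#'
#' @param path GraphML file, or the prefix used for a CSV pair.
#' @param format `"graphml"` or `"csv_pair"`.
#' @return A `knowledge_graph`.
#' @export
read_graph_file <- function(path, format = c("graphml", "csv_pair")) {
  format <- match.arg(format)
  if (format == "graphml") {
    doc <- xml2::read_xml(path)
    xml2::xml_ns_strip(doc)
    node_els <- xml2::xml_find_all(doc, ".//node")
    get_data <- function(el, key) {
      d <- xml2::xml_find_first(el, sprintf("./data[@key='%s']", key))
      if (inherits(d, "xml_missing")) NA_character_ else xml2::xml_text(d)
    }
    nodes <- tibble::tibble(
      node_id = xml2::xml_attr(node_els, "id"),
      kind = vapply(node_els, get_data, character(1), "kind"),
      label = vapply(node_els, get_data, character(1), "label"),
      frequency = as.numeric(vapply(node_els, get_data, character(1),
                                    "frequency")),
      source = vapply(node_els, get_data, character(1), "nsource")
    )
    edge_els <- xml2::xml_find_all(doc, ".//edge")
    edges <- tibble::tibble(
      edge_id = xml2::xml_attr(edge_els, "id"),
      from = xml2::xml_attr(edge_els, "source"),
      to = xml2::xml_attr(edge_els, "target"),
      relation = vapply(edge_els, get_data, character(1), "relation"),
      weight = as.numeric(vapply(edge_els, get_data, character(1), "weight"))
    )
    graph_source <- xml2::xml_attr(xml2::xml_find_first(doc, ".//graph"), "id")
  } else {
    nodes <- tibble::as_tibble(utils::read.csv(
      paste0(path, "_nodes.csv"), colClasses = c(frequency = "numeric"),
      na.strings = ""))
    edges <- tibble::as_tibble(utils::read.csv(
      paste0(path, "_edges.csv"), colClasses = c(weight = "numeric"),
      na.strings = ""))
    edges$edge_id <- paste(edges$relation, edges$from, edges$to, sep = "|")
    edges <- edges[, c("edge_id", "from", "to", "relation", "weight")]
    graph_source <- paste(unique(nodes$source), collapse = "+")
  }
  nodes$ref <- ref_from_node_id(nodes$node_id, nodes$kind, nodes$source)
  cond_ref <- unique(nodes$ref[nodes$kind == "condition"])
  structure(
    list(nodes = nodes, edges = edges,
         condition_id = if (length(cond_ref)) cond_ref[1] else NA_character_,
         source = graph_source, top_k = NA_integer_),
    class = "knowledge_graph"
  )
}

#' @export
print.knowledge_graph <- function(x, ...) {
  cat(sprintf(
    "<knowledge_graph> source '%s', condition '%s': %d nodes (%d concepts, %d types), %d edges\n",
    x$source, x$condition_id, nrow(x$nodes),
    sum(x$nodes$kind == "concept"), sum(x$nodes$kind == "semantic_type"),
    nrow(x$edges)))
  invisible(x)
}
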