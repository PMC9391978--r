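test_that("the graph materializes the schema with the right structural counts", {
  sel <- mk_selection(n_types = 3L, n_per = 25L, source = "forum")
  kg <- build_kg(sel)
  expect_identical(nrow(kg$nodes), 1L + 3L + 75L)
  expect_identical(sum(kg$edges$relation == "isA"), 75L)
  expect_identical(sum(kg$edges$relation == "isRelatedTo"), 3L)
  expect_identical(nrow(kg$edges), 78L)
  cond <- kg$nodes[kg$nodes$kind == "condition", ]
  expect_equal(cond$frequency, 1)
  expect_true(all(startsWith(kg$nodes$node_id, "forum:")))
  expect_silent(validate_kg(kg))
  expect_error(build_kg(structure(list(), class = "ranked_selection",
                                  condition_id = "X", source = "s",
                                  top_k = 25L)),
               "empty")
})

test_that("semantic-type node frequency is the mean over its selected concepts", {
  sel <- mk_selection(n_types = 1L, n_per = 25L)
  sel$type1 <- sel$type1[1:2, ]
  sel$type1$frequency <- c(0.2, 0.4)
  rel_weights <- sel$type1$relatedness
  kg <- build_kg(sel)
  tn <- kg$nodes[kg$nodes$kind == "semantic_type", ]
  expect_equal(tn$frequency, 0.3)
  # a single selected concept: mean of one
  sel$type1 <- sel$type1[1, ]
  sel$type1$frequency <- 0.4
  expect_equal(build_kg(sel)$nodes$frequency[
    build_kg(sel)$nodes$kind == "semantic_type"], 0.4)
  # isA weights carry the relatedness scores
  isa <- kg$edges[kg$edges$relation == "isA", ]
  expect_equal(sort(isa$weight), sort(rel_weights), tolerance = 1e-12)
})

test_that("sameAs links exactly the concepts selected in both graphs", {
  sel_a <- mk_selection(n_types = 2L, n_per = 10L, source = "forum")
  sel_b <- mk_selection(n_types = 2L, n_per = 10L, source = "pubmed")
  # rename 13 of b's 20 concepts so the overlap is exactly 7
  ren <- 0L
  for (t in names(sel_b)) {
    g <- sel_b[[t]]
    for (i in seq_len(nrow(g))) {
      if (ren < 13L) {
        g$concept_id[i] <- paste0("ONLY_B_", ren)
        g$name[i] <- g$concept_id[i]
        ren <- ren + 1L
      }
    }
    sel_b[[t]] <- g
  }
  kg_a <- build_kg(sel_a); kg_b <- build_kg(sel_b)
  merged <- link_same_as(kg_a, kg_b)
  expect_identical(merged$sameas_count, 7L)
  expect_identical(nrow(merged$edges),
                   nrow(kg_a$edges) + nrow(kg_b$edges) + 7L)
  expect_true(all(is.na(merged$edges$weight[merged$edges$relation == "sameAs"])))
  expect_silent(validate_kg(merged))
  # merging is symmetric up to ids: same counts either way
  flipped <- link_same_as(kg_b, kg_a)
  expect_identical(flipped$sameas_count, merged$sameas_count)
  expect_setequal(flipped$nodes$node_id, merged$nodes$node_id)
  expect_identical(nrow(flipped$edges), nrow(merged$edges))
  expect_error(link_same_as(kg_a, kg_a), "same source")
})

test_that("disjoint selections merge with zero sameAs edges", {
  sel_a <- mk_selection(n_types = 1L, n_per = 3L, source = "forum")
  sel_b <- mk_selection(n_types = 1L, n_per = 3L, source = "pubmed")
  sel_b$type1$concept_id <- paste0("Z", sel_b$type1$concept_id)
  sel_b$type1$name <- sel_b$type1$concept_id
  merged <- link_same_as(build_kg(sel_a), build_kg(sel_b))
  expect_identical(merged$sameas_count, 0L)
  expect_identical(sum(merged$edges$relation == "sameAs"), 0L)
})

test_that("the validator catches perturbed graphs", {
  kg <- build_kg(mk_selection(n_types = 2L, n_per = 4L))
  bad <- kg
  bad$edges <- bad$edges[-(which(bad$edges$relation == "isA")[1]), ]
  expect_error(validate_kg(bad), "exactly one isA")

  bad <- kg
  bad$edges$weight[bad$edges$relation == "isRelatedTo"] <- 0.5
  expect_error(validate_kg(bad), "weights")

  bad <- kg
  bad$edges$weight[bad$edges$relation == "isA"][1] <- NA_real_
  expect_error(validate_kg(bad), "weights")

  bad <- kg
  bad$nodes$frequency[2] <- 1.7
  expect_error(validate_kg(bad), "frequency")

  bad <- kg
  extra <- bad$edges[bad$edges$relation == "isRelatedTo", ][1, ]
  extra$edge_id <- "dup"
  bad$edges <- rbind(bad$edges, extra)
  expect_error(validate_kg(bad), "isRelatedTo")

  bad <- kg
  bad$top_k <- 2L
  expect_error(validate_kg(bad), "top_k")
})

test_that("GraphML round-trips with identical attributes and omitted empty weights", {
  sel_a <- mk_selection(n_types = 2L, n_per = 5L, source = "forum")
  sel_b <- mk_selection(n_types = 2L, n_per = 5L, source = "pubmed")
  kg <- link_same_as(build_kg(sel_a), build_kg(sel_b))
  d <- withr::local_tempdir()
  path <- file.path(d, "kg.graphml")
  export_graph(kg, path, format = "graphml")

  # unweighted edges must not carry a weight element at all
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  rel_edges <- xml2::xml_find_all(
    doc, ".//edge[data[@key='relation'] != 'isA']")
  expect_gt(length(rel_edges), 0)
  expect_length(xml2::xml_find_all(rel_edges, "./data[@key='weight']"), 0L)

  back <- read_graph_file(path, format = "graphml")
  expect_equal(as.data.frame(back$nodes), as.data.frame(kg$nodes),
               tolerance = 1e-12)
  expect_equal(as.data.frame(back$edges), as.data.frame(kg$edges),
               tolerance = 1e-12)
  expect_identical(back$condition_id, kg$condition_id)

  # independent reader agrees on the topology
  ig <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(ig), nrow(kg$nodes))
  expect_equal(igraph::ecount(ig), nrow(kg$edges))
  expect_setequal(igraph::vertex_attr(ig, "label"), unique(kg$nodes$label))
})

test_that("the CSV pair round-trips and counts its rows", {
  kg <- build_kg(mk_selection(n_types = 3L, n_per = 25L, source = "forum"))
  d <- withr::local_tempdir()
  paths <- export_graph(kg, file.path(d, "kg"), format = "csv_pair")
  nodes_csv <- utils::read.csv(file.path(d, "kg_nodes.csv"))
  expect_identical(nrow(nodes_csv), 79L)  # 1 condition + 3 types + 75
  expect_identical(names(nodes_csv),
                   c("node_id", "kind", "label", "frequency", "source"))
  edges_csv <- utils::read.csv(file.path(d, "kg_edges.csv"), na.strings = "")
  expect_identical(names(edges_csv), c("from", "to", "relation", "weight"))
  expect_true(all(is.na(edges_csv$weight[edges_csv$relation != "isA"])))
  back <- read_graph_file(file.path(d, "kg"), format = "csv_pair")
  expect_equal(as.data.frame(back$nodes), as.data.frame(kg$nodes),
               tolerance = 1e-12)
  expect_equal(as.data.frame(back$edges), as.data.frame(kg$edges),
               tolerance = 1e-12)
})
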