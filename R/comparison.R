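#' Per-concept relatedness differences between two corpora
#'
#' Joins two relatedness tables for the same condition on their common
#' concepts and computes, per concept, the score difference
#' `diff = FR - PR` (first source minus second). The mean and the
#' population standard deviation (divisor n) of the differences are stored
#' for the classification step. Concepts present in only one corpus have no
#' score difference and are reported separately as source-exclusive.
#'
#' @param rel_a Relatedness table for the first corpus (e.g. forum, "FR").
#' @param rel_b Relatedness table for the second corpus (e.g. PubMed, "PR").
#' @param restrict_to Optional character vector of concept ids; when given
#'   (typically the union of both top-k selections), rows are limited to it.
#' @return A tibble of class `comparison_table` with columns `concept_id`,
#'   `name`, `semantic_type`, `FR`, `PR`, `diff`; attributes `mu`, `sigma`,
#'   `condition_id`, `sources`, `exclusive_a`, `exclusive_b`.
#' @export
score_differences <- function(rel_a, rel_b, restrict_to = NULL) {
  stopifnot(inherits(rel_a, "relatedness_table"),
            inherits(rel_b, "relatedness_table"))
  if (!identical(attr(rel_a, "condition_id"), attr(rel_b, "condition_id"))) {
    stopf("tables reference different conditions ('%s' vs '%s')",
          attr(rel_a, "condition_id"), attr(rel_b, "condition_id"))
  }
  a <- tibble::as_tibble(rel_a)[, c("concept_id", "name", "semantic_type",
                                    "relatedness")]
  b <- tibble::as_tibble(rel_b)[, c("concept_id", "relatedness")]
  names(a)[4] <- "FR"; names(b)[2] <- "PR"
  joint <- dplyr::inner_join(a, b, by = "concept_id")
  if (!is.null(restrict_to)) {
    joint <- joint[joint$concept_id %in% restrict_to, , drop = FALSE]
  }
  if (nrow(joint) == 0L) {
    stopf("the two corpora share no scored concepts")
  }
  joint$diff <- joint$FR - joint$PR
  joint <- joint[order(joint$concept_id, method = "radix"), ]
  mu <- mean(joint$diff)
  sigma <- sqrt(mean((joint$diff - mu)^2))  # population sd
  structure(joint, class = c("comparison_table", class(tibble::tibble())),
            mu = mu, sigma = sigma,
            condition_id = attr(rel_a, "condition_id"),
            sources = c(attr(rel_a, "source"), attr(rel_b, "source")),
            exclusive_a = setdiff(rel_a$concept_id, rel_b$concept_id),
            exclusive_b = setdiff(rel_b$concept_id, rel_a$concept_id))
}

#' Classify concepts as convergent or divergent priorities
#'
#' Applies the two-standard-deviation rule to the score differences: a
#' concept with `diff > mu + 2*sigma` is a priority of the first corpus
#' (`forum_priority`), one with `diff < mu - 2*sigma` a priority of the
#' second (`pubmed_priority`), and everything in between — boundaries
#' included, since the priority rules are strict inequalities — is of
#' `similar` relevance to both. With `sigma = 0` every concept is similar.
#'
#' @param table A `comparison_table` from [score_differences()].
#' @return The table with a `category` column added and attributes `lower`
#'   and `upper` holding the thresholds.
#' @export
classify_concepts <- function(table) {
  stopifnot(inherits(table, "comparison_table"))
  mu <- attr(table, "mu"); sigma <- attr(table, "sigma")
  upper <- mu + 2 * sigma
  lower <- mu - 2 * sigma
  table$category <- ifelse(table$diff > upper, "forum_priority",
                    ifelse(table$diff < lower, "pubmed_priority", "similar"))
  attr(table, "upper") <- upper
  attr(table, "lower") <- lower
  table
}

#' Write a classified comparison table with its summary block
#'
#' TSV of the per-concept rows followed by (as a separate `.summary.tsv`)
#' the mean, standard deviation, thresholds and per-category counts.
#'
#' @param table A classified `comparison_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_comparison <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  counts <- table(factor(table$category,
                         levels = c("similar", "forum_priority",
                                    "pubmed_priority")))
  summary_df <- data.frame(
    statistic = c("mu", "sigma", "lower", "upper",
                  paste0("n_", names(counts)), "n_total"),
    value = c(attr(table, "mu"), attr(table, "sigma"),
              attr(table, "lower"), attr(table, "upper"),
              as.numeric(counts), nrow(table))
  )
  utils::write.table(summary_df, paste0(path, ".summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
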