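#' Fisher exact term enrichment of a gene set
#'
#' For every term annotating at least one universe gene, a one-sided
#' Fisher exact test (hypergeometric upper tail) for over-representation
#' of the term in the gene set, ranked by ascending p. No multiple-testing
#' correction is applied to the primary p-value (raw p-values are
#' reported, Table-1 style); a Benjamini-Hochberg column is emitted
#' alongside.
#'
#' @param gene_set Character vector of gene ids (subset of the universe).
#' @param universe Character vector of background gene ids.
#' @param terms Tibble `gene_id`, `term_id` (optionally `term_name`,
#'   `ontology`).
#' @return A `medip_enrichment` tibble: term_id, term_name, ontology,
#'   set_count, set_size, bg_count, universe_size, p_value, p_adjust,
#'   ranked by p.
#' @export
#' @examples
#' terms <- tibble::tibble(gene_id = paste0("g", 1:5), term_id = "T1")
#' fisher_enrichment(paste0("g", 1:5), paste0("g", 1:20), terms)
fisher_enrichment <- function(gene_set, universe, terms) {
  universe <- unique(universe)
  gene_set <- unique(gene_set)
  if (!length(gene_set) || !length(universe)) {
    abort("gene set and universe must be non-empty")
  }
  if (!all(gene_set %in% universe)) {
    abort("gene set must be a subset of the universe")
  }
  terms <- terms[terms$gene_id %in% universe, ]
  n_univ <- length(universe)
  n_set <- length(gene_set)
  per_term <- terms |>
    group_by(.data$term_id) |>
    summarise(
      term_name = if ("term_name" %in% names(terms))
        dplyr::first(.data$term_name) else NA_character_,
      ontology = if ("ontology" %in% names(terms))
        dplyr::first(.data$ontology) else NA_character_,
      bg_count = dplyr::n_distinct(.data$gene_id),
      set_count = dplyr::n_distinct(intersect(.data$gene_id, gene_set)),
      .groups = "drop"
    ) |>
    filter(.data$bg_count > 0)
  per_term <- per_term |>
    mutate(
      set_size = n_set,
      universe_size = n_univ,
      p_value = phyper(.data$set_count - 1L, .data$bg_count,
                       n_univ - .data$bg_count, n_set, lower.tail = FALSE),
      p_adjust = p.adjust(.data$p_value, method = "BH")
    ) |>
    arrange(.data$p_value, .data$term_id) |>
    select("term_id", "term_name", "ontology", "set_count", "set_size",
           "bg_count", "universe_size", "p_value", "p_adjust")
  structure(per_term, class = c("medip_enrichment", class(tibble())))
}

#' Top enriched terms, Table-1 style
#' @param x A [fisher_enrichment()] result.
#' @param n Number of terms (default 10).
#' @return The `n` most enriched terms.
#' @export
top_enrichment <- function(x, n = 10) head(x, n)

#' Term enrichment per kinetics cluster
#'
#' Runs [fisher_enrichment()] for each cluster's gene set against the
#' clustered-gene universe and computes the pairwise Jaccard overlap of
#' the clusters' significant term sets (p < `alpha`). Clusters smaller
#' than `min_size` are skipped with a warning.
#'
#' @param clusters A [cluster_kinetics()] result.
#' @param terms Tibble `gene_id`, `term_id` (+ optional name/ontology).
#' @param universe Background gene set; defaults to all clustered genes.
#' @param alpha Significance threshold defining a cluster's term set.
#' @param min_size Minimum cluster size (default 5).
#' @return List: `enrichment` (named list of per-cluster results) and
#'   `overlap` (Jaccard matrix of significant term sets).
#' @export
cluster_term_profiles <- function(clusters, terms, universe = NULL,
                                  alpha = 0.05, min_size = 5) {
  asg <- clusters$assignments
  universe <- universe %||% asg$gene_id
  ids <- sort(unique(asg$cluster))
  enr <- list()
  sig_terms <- list()
  for (cl in ids) {
    members <- asg$gene_id[asg$cluster == cl]
    key <- as.character(cl)
    if (length(members) < min_size) {
      warn(sprintf("cluster %s has fewer than %d genes; enrichment skipped",
                   key, min_size))
      next
    }
    e <- fisher_enrichment(members, universe, terms)
    enr[[key]] <- e
    sig_terms[[key]] <- e$term_id[e$p_value < alpha]
  }
  labs <- names(enr)
  overlap <- matrix(NA_real_, length(labs), length(labs),
                    dimnames = list(labs, labs))
  for (i in seq_along(labs)) {
    for (j in seq_along(labs)) {
      a <- sig_terms[[labs[i]]]
      b <- sig_terms[[labs[j]]]
      u <- union(a, b)
      overlap[i, j] <- if (length(u)) length(intersect(a, b)) / length(u) else
        if (i == j) 1 else 0
    }
  }
  list(enrichment = enr, overlap = overlap)
}
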