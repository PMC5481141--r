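#' Simulate a stage-matched gene expression table
#'
#' Produces an RPKM-like genes x stages expression matrix with the
#' methylation-expression structure the downstream analyses look for:
#' * unmethylated genes are mostly silent (near-zero, noisy expression);
#' * methylated genes draw a base expression level monotone in their mean
#'   CDS methylation;
#' * the truth's coupled genes have stage kinetics proportional to their
#'   CDS methylation kinetics (plus mild log-normal noise), so their
#'   methylation-expression correlation is positive by construction;
#' * other genes' stage kinetics are independent of methylation.
#'
#' @param truth A [simulate_truth()] result.
#' @param config The matching [simulation_config()].
#' @return Tibble: `gene_id` then one expression column per stage.
#' @export
simulate_expression <- function(truth, config) {
  with_substream(config$seed, "expression", {
    stages <- config$stages
    genes <- truth$genes
    mu <- tbl_to_matrix(truth$mu)
    el_ids <- rownames(mu)

    # per-gene mean CDS methylation kinetics from the truth intensities
    cds_rows <- grepl("_CDS", el_ids, fixed = TRUE)
    cds_gene <- sub("_CDS.*$", "", el_ids[cds_rows])
    kin_sum <- rowsum(mu[cds_rows, , drop = FALSE], cds_gene)
    kin_n <- as.vector(table(cds_gene)[rownames(kin_sum)])
    kin_mat <- kin_sum / kin_n

    out <- matrix(0, nrow = nrow(genes), ncol = length(stages),
                  dimnames = list(genes$gene_id, stages))
    for (i in seq_len(nrow(genes))) {
      gid <- genes$gene_id[i]
      kin <- if (gid %in% rownames(kin_mat)) kin_mat[gid, ] else
        rep(0, length(stages))
      if (!genes$methylated[i]) {
        out[i, ] <- rlnorm(1, log(0.05), 1) * rlnorm(length(stages), 0, 0.3)
        next
      }
      m_g <- mean(kin)
      base <- 3 * (max(m_g, 0.01) / config$mean_cpm_methylated)^0.8 *
        rlnorm(1, 0, 0.5)
      if (genes$coupled[i] && m_g > 0) {
        out[i, ] <- base * (kin / m_g) * rlnorm(length(stages), 0, 0.15)
      } else if (genes$dynamic[i]) {
        out[i, ] <- base * rlnorm(length(stages), 0, 0.5)
      } else {
        out[i, ] <- base * rlnorm(length(stages), 0, 0.2)
      }
    }
    matrix_to_tbl(out, "gene_id")
  })
}

#' Generate a synthetic gene-to-term annotation table
#'
#' Assigns background functional terms to genes at random (each term has its
#' own background frequency), optionally planting one or more terms as
#' over-represented in designated gene sets so enrichment recovery can be
#' tested against a known answer.
#'
#' @param annotation A [medip_annotation()] (the gene universe).
#' @param n_terms Number of background terms.
#' @param planted_enrichment Optional list of `list(term_id =, genes =,
#'   prob =)` entries: each named term is added to the listed genes with
#'   probability `prob` (on top of its background rate).
#' @param seed Integer seed.
#' @return Tibble with `gene_id`, `term_id`, `term_name`, `ontology`.
#' @export
simulate_term_annotations <- function(annotation, n_terms = 50,
                                      planted_enrichment = NULL, seed = 1L) {
  genes <- unique(annotation$elements$gene_id)
  genes <- sort(genes[!is.na(genes)])
  with_substream(seed, "terms", {
    term_ids <- sprintf("term_%04d", seq_len(n_terms))
    bg_prob <- runif(n_terms, 0.01, 0.08)
    rows <- vector("list", n_terms + length(planted_enrichment))
    for (t in seq_len(n_terms)) {
      hit <- genes[runif(length(genes)) < bg_prob[t]]
      if (length(hit)) {
        rows[[t]] <- tibble(gene_id = hit, term_id = term_ids[t])
      }
    }
    k <- n_terms
    for (pl in planted_enrichment %||% list()) {
      k <- k + 1L
      hit <- pl$genes[runif(length(pl$genes)) < (pl$prob %||% 0.9)]
      if (length(hit)) {
        rows[[k]] <- tibble(gene_id = hit, term_id = pl$term_id)
      }
    }
    out <- bind_rows(rows) |> dplyr::distinct()
    out |>
      mutate(
        term_name = sub("term_", "process ", .data$term_id),
        ontology = "BP"
      ) |>
      arrange(.data$term_id, .data$gene_id)
  })
}
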