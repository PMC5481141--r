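#' Write called DMRs as BED6+
#'
#' Columns: chrom, start, end, name (`step:index`), score (-log10 region
#' p, capped at 350), strand (`.`), then log2FC, direction and the
#' comma-separated annotated element ids.
#'
#' @param dmrs An annotated or plain DMR tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dmrs <- function(dmrs, path) {
  d <- as_tibble(dmrs)
  ann_col <- if ("annotations" %in% names(d)) {
    vapply(d$annotations, function(x) paste(x, collapse = ","), "")
  } else {
    rep("", nrow(d))
  }
  out <- tibble(
    chrom = d$scaffold, start = d$start, end = d$end,
    name = paste0(d$step, ":", seq_len(max(1, nrow(d)))[seq_len(nrow(d))]),
    score = round(pmin(350, -log10(pmax(d$p_value, 1e-350))), 2),
    strand = ".",
    log2fc = round(d$log2fc, 4), direction = d$direction,
    annotations = ann_col
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Configuration for the end-to-end pipeline
#'
#' Collects the analysis thresholds (each defaulting to the study's
#' published setting), the input paths or the simulation config, and the
#' output directory.
#'
#' @param out_dir Output directory.
#' @param simulate Logical; generate inputs with the synthetic-data module.
#' @param sim_config A [simulation_config()] (used when `simulate`).
#' @param paths Named list of input paths (`annotation`, `counts`,
#'   `samples`, `expression`, `terms`) when not simulating.
#' @param call_min_cpm,call_min_replicates Methylation-call thresholds.
#' @param window_width,window_step,window_p,min_lfc,region_p,min_region_length
#'   DMR-caller parameters.
#' @param scaffold_min_length,scaffold_max_n Scaffold selection.
#' @param dynamic_alpha ANOVA selection threshold.
#' @param k_clusters K-means cluster count.
#' @param coupling_alpha Kinetics-correlation coupling threshold.
#' @param association_radius DMR-gene association radius (bp).
#' @param write_fragments Also write per-sample fragment BEDs (large).
#' @param seed Master seed; overrides `sim_config$seed` when simulating.
#' @return A `medip_pipeline_config` list.
#' @export
pipeline_config <- function(out_dir, simulate = TRUE,
                            sim_config = simulation_config(),
                            paths = list(),
                            call_min_cpm = 1, call_min_replicates = 2,
                            window_width = 1000, window_step = 100,
                            window_p = 1e-4, min_lfc = 1, region_p = 1e-7,
                            min_region_length = 1000,
                            scaffold_min_length = 44000, scaffold_max_n = 2000,
                            dynamic_alpha = 0.01, k_clusters = 5,
                            coupling_alpha = 0.05, association_radius = 1e5,
                            write_fragments = FALSE, seed = NULL) {
  if (!is.null(seed)) {
    sim_config$seed <- as.integer(seed)
  }
  structure(list(
    out_dir = out_dir, simulate = simulate, sim_config = sim_config,
    paths = paths, call_min_cpm = call_min_cpm,
    call_min_replicates = call_min_replicates,
    window_width = window_width, window_step = window_step,
    window_p = window_p, min_lfc = min_lfc, region_p = region_p,
    min_region_length = min_region_length,
    scaffold_min_length = scaffold_min_length,
    scaffold_max_n = scaffold_max_n, dynamic_alpha = dynamic_alpha,
    k_clusters = k_clusters, coupling_alpha = coupling_alpha,
    association_radius = association_radius,
    write_fragments = write_fragments,
    seed = sim_config$seed
  ), class = c("medip_pipeline_config", "list"))
}

pipeline_log <- function(stage, event, ...) {
  extra <- list(...)
  kv <- if (length(extra)) {
    paste(sprintf("%s=%s", names(extra), unlist(extra)), collapse = " ")
  } else ""
  inform(sprintf("[%s] %s %s", stage, event, kv))
}

#' Run the full methylome-dynamics pipeline
#'
#' Orchestrates the stages end-to-end: input simulation (or loading),
#' quantification and methylation calls, DMR detection at the C, I and M
#' steps with annotation, distances and TE-class contingency, stage
#' kinetics (ANOVA selection, K-means clustering, persistence, physical
#' map), methylation-expression linkage, and term enrichment. All tabular
#' outputs are written under `config$out_dir` together with a summary
#' (`summary.json`), the echoed configuration, a provenance block and an
#' md5 manifest. Re-running with the same config and seed reproduces every
#' data output byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return A `medip_pipeline_result` list of all stage results, invisibly.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  cfg_echo <- config
  cfg_echo$sim_config <- unclass(cfg_echo$sim_config)
  jsonlite::write_json(unclass(cfg_echo), out("config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)

  # ---- inputs -------------------------------------------------------------
  if (config$simulate) {
    sim <- config$sim_config
    pipeline_log("simulate", "generating synthetic experiment", seed = sim$seed)
    annotation0 <- simulate_annotation(sim)
    truth <- simulate_truth(annotation0, sim)
    counts <- simulate_counts(truth, annotation0, sim)
    expression <- simulate_expression(truth, sim)
    write_annotation(annotation0, out("annotation.gff3"), "gff3")
    write_annotation(annotation0, out("annotation.bed"), "bed")
    write_counts(counts, out("counts.tsv"), out("samples.tsv"))
    readr::write_tsv(expression, out("expression.tsv"))
    readr::write_tsv(truth$dmrs, out("truth_dmrs.tsv"))
    readr::write_tsv(truth$genes, out("truth_genes.tsv"))
  } else {
    p <- config$paths
    for (need in c("annotation", "counts", "samples", "expression")) {
      if (is.null(p[[need]]) || !file.exists(p[[need]])) {
        abort(sprintf("missing input file for '%s'", need))
      }
    }
    truth <- NULL
    counts <- read_counts(p$counts, p$samples)
    expression <- readr::read_tsv(p$expression, show_col_types = FALSE)
  }

  annotation <- if (config$simulate) {
    read_annotation(out("annotation.gff3"), "gff3")
  } else {
    read_annotation(config$paths$annotation)
  }

  # drop counts for elements removed on read (e.g. short promoters)
  counts <- medip_counts(
    counts$counts[counts$counts$element_id %in%
                    annotation$elements$element_id, ],
    counts$samples
  )

  # ---- quantification -----------------------------------------------------
  pipeline_log("quantify", "cpm normalisation and methylation calls")
  norm <- cpm_normalize(counts)
  calls <- call_methylated(norm, annotation,
                           min_cpm = config$call_min_cpm,
                           min_replicates = config$call_min_replicates)
  distr <- methylation_distribution(norm, annotation)
  pattern <- gbm_pattern_ratio(norm, annotation)
  readr::write_tsv(norm$cpm, out("cpm.tsv"))
  readr::write_tsv(calls$elements, out("calls_elements.tsv"))
  readr::write_tsv(calls$genes, out("calls_genes.tsv"))
  readr::write_tsv(distr$proportions, out("class_proportions.tsv"))

  # ---- DMRs ---------------------------------------------------------------
  sel <- select_scaffolds(annotation, config$scaffold_min_length,
                          config$scaffold_max_n)
  pipeline_log("dmr", "scaffold selection", n = nrow(sel),
               genome_fraction = round(attr(sel, "genome_fraction"), 3))
  dmr_steps <- list()
  bins <- NULL
  if (nrow(sel) && config$simulate) {
    fragments <- simulate_fragments(truth, annotation0, config$sim_config,
                                    scaffolds = sel$scaffold)
    if (config$write_fragments) write_fragments(fragments, out("fragments"))
    bins <- bin_fragments(fragments, sel,
                          sample_ids = counts$samples$sample_id)
    windows <- window_counts(bins, config$window_width, config$window_step)
    for (st in c("C", "I", "M")) {
      dmr_steps[[st]] <- detect_dmrs(
        windows, counts$samples, step_design(st),
        window_p = config$window_p, min_lfc = config$min_lfc,
        region_p = config$region_p, min_length = config$min_region_length
      )
      pipeline_log("dmr", "step called", step = st, n = nrow(dmr_steps[[st]]))
    }
  }
  dmrs <- bind_rows(lapply(dmr_steps, as_tibble))
  annotated <- NULL; te_cont <- NULL; distances <- NULL
  if (nrow(dmrs)) {
    annotated <- annotate_dmrs(dmrs, annotation)
    te_cont <- te_class_contingency(annotated, annotation)
    distances <- distance_to_nearest_dmr(annotation, dmrs)
    write_dmrs(annotated$dmrs, out("dmrs.bed"))
    readr::write_tsv(annotated$tally, out("dmr_annotation_tally.tsv"))
    readr::write_tsv(distances$class_means, out("dmr_distance_means.tsv"))
  }

  # ---- dynamics -----------------------------------------------------------
  pipeline_log("dynamics", "ANOVA selection and clustering")
  dynamics <- anova_dynamic_selection(norm, annotation,
                                      alpha = config$dynamic_alpha,
                                      posthoc = FALSE)
  clusters <- NULL
  n_dyn <- sum(dynamics$genes$dynamic)
  if (n_dyn >= config$k_clusters) {
    clusters <- cluster_kinetics(dynamics, k = config$k_clusters,
                                 seed = config$seed)
  }
  pers <- persistence(calls)
  pmap <- NULL
  if (!is.null(bins) && nrow(sel)) {
    pmap <- physical_map(
      bins, counts$samples, sel$scaffold[1], width = 10000,
      pool = list(oocyte = "oocyte", cells_2_8 = "cells_2_8",
                  intermediate = medip_midlarval_stages(), spat = "spat")
    )
    readr::write_tsv(as_tibble(pmap), out("physical_map.tsv"))
  }
  kin_tbl <- dynamics$profiles |>
    left_join(dynamics$genes, by = "gene_id")
  if (!is.null(clusters)) {
    kin_tbl <- kin_tbl |> left_join(clusters$assignments, by = "gene_id")
  }
  readr::write_tsv(kin_tbl, out("kinetics.tsv"))

  # ---- expression linkage -------------------------------------------------
  pipeline_log("link", "methylation-expression analyses")
  status <- expression_by_methylation_status(calls, expression)
  meth_any <- calls$genes$gene_id[rowSums(as.matrix(calls$genes[, -1])) > 0]
  meth_level <- dynamics$profiles |>
    filter(.data$gene_id %in% meth_any) |>
    mutate(methylation = rowMeans(across(-"gene_id"))) |>
    select("gene_id", "methylation")
  deciles <- if (nrow(meth_level) >= 10) {
    decile_trends(meth_level, expression)
  }
  pat_expr <- tryCatch(pattern_vs_expression(pattern, expression),
                       error = function(e) NULL)
  dyn_profiles <- dynamics$profiles |>
    filter(.data$gene_id %in% dynamics$genes$gene_id[dynamics$genes$dynamic])
  kin_cor <- if (nrow(dyn_profiles) >= 3) {
    kinetics_correlation(dyn_profiles, expression,
                         alpha = config$coupling_alpha)
  }
  proximity <- if (nrow(dmrs)) {
    dmr_proximity_expression(dmrs, annotation, expression,
                             radius = config$association_radius)
  }
  if (!is.null(kin_cor)) readr::write_tsv(tidy(kin_cor), out("coupling.tsv"))
  if (!is.null(deciles)) {
    readr::write_tsv(deciles$by_level, out("deciles_level.tsv"))
    readr::write_tsv(deciles$by_cv, out("deciles_cv.tsv"))
  }

  # ---- enrichment ---------------------------------------------------------
  terms <- if (config$simulate) {
    dmr_genes_c <- dmr_gene_set(annotated, annotation, "C")
    simulate_term_annotations(
      annotation, n_terms = 50,
      planted_enrichment = if (length(dmr_genes_c) >= 3) {
        list(list(term_id = "term_planted_C", genes = dmr_genes_c,
                  prob = 1))
      },
      seed = config$seed
    )
  } else if (!is.null(config$paths$terms)) {
    readr::read_tsv(config$paths$terms, show_col_types = FALSE)
  }
  enrichment <- list()
  if (!is.null(terms)) {
    readr::write_tsv(terms, out("terms.tsv"))
    universe <- sort(unique(annotation$elements$gene_id))
    universe <- universe[!is.na(universe)]
    for (st in names(dmr_steps)) {
      gs <- dmr_gene_set(annotated, annotation, st)
      if (length(gs) >= 2) {
        enrichment[[st]] <- fisher_enrichment(gs, universe, terms)
        readr::write_tsv(top_enrichment(enrichment[[st]]),
                         out(sprintf("enrichment_%s.tsv", st)))
      }
    }
    if (!is.null(clusters)) {
      enrichment$clusters <- suppressWarnings(
        cluster_term_profiles(clusters, terms)
      )
    }
  }

  # ---- summary, provenance, manifest --------------------------------------
  g_calls <- glance(calls)
  summary <- list(
    seed = config$seed,
    n_scaffolds_selected = nrow(sel),
    dmr_counts = lapply(dmr_steps, nrow),
    methylated_genes = g_calls$methylated_genes,
    unmethylated_genes = g_calls$unmethylated_genes,
    persistence_fraction = round(pers$fraction, 6),
    dynamic_fraction = round(mean(dynamics$genes$dynamic), 6),
    coupled_fraction = if (!is.null(kin_cor)) {
      round(attr(kin_cor, "coupled_fraction"), 6)
    },
    expression_wilcox_p = signif(status$p_value, 6),
    top_terms = lapply(enrichment[intersect(names(enrichment), c("C", "M"))],
                       function(e) head(e$term_id, 5))
  )
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(c(
    sprintf("medipdyn version: %s",
            as.character(utils::packageVersion("medipdyn"))),
    sprintf("seed: %d", config$seed),
    sprintf("timestamp: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  ), out("provenance.txt"))
  files <- setdiff(list.files(config$out_dir, recursive = TRUE),
                   c("manifest.tsv", "provenance.txt"))
  manifest <- tibble(
    file = files,
    md5 = unname(tools::md5sum(file.path(config$out_dir, files)))
  )
  readr::write_tsv(manifest, out("manifest.tsv"))
  pipeline_log("done", "pipeline complete", outputs = nrow(manifest))

  invisible(structure(list(
    config = config, annotation = annotation, truth = truth, counts = counts,
    norm = norm, calls = calls, distribution = distr, pattern = pattern,
    dmrs = dmr_steps, annotated_dmrs = annotated, te_contingency = te_cont,
    distances = distances, dynamics = dynamics, clusters = clusters,
    persistence = pers, physical_map = pmap, expression = expression,
    expression_status = status, deciles = deciles,
    pattern_expression = pat_expr, kinetics_correlation = kin_cor,
    proximity = proximity, enrichment = enrichment, summary = summary
  ), class = c("medip_pipeline_result", "list")))
}

# genes with >= 1 element fully covered by a DMR of the given step
dmr_gene_set <- function(annotated, annotation, step) {
  if (is.null(annotated)) return(character())
  d <- annotated$dmrs
  ids <- unlist(d$annotations[d$step == step])
  g <- annotation$elements$gene_id[match(ids, annotation$elements$element_id)]
  sort(unique(g[!is.na(g)]))
}

#' Verify the output manifest of a pipeline run
#'
#' Recomputes the md5 of every file listed in `manifest.tsv` and compares.
#'
#' @param out_dir A pipeline output directory.
#' @return TRUE if all hashes match; otherwise an error listing mismatches.
#' @export
verify_manifest <- function(out_dir) {
  mf <- readr::read_tsv(file.path(out_dir, "manifest.tsv"),
                        show_col_types = FALSE)
  now <- unname(tools::md5sum(file.path(out_dir, mf$file)))
  bad <- mf$file[is.na(now) | now != mf$md5]
  if (length(bad)) {
    abort(paste("manifest mismatch for:", paste(bad, collapse = ", ")))
  }
  TRUE
}

#' @export
print.medip_pipeline_result <- function(x, ...) {
  cat("<medip_pipeline_result>\n")
  cat(jsonlite::toJSON(x$summary, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA), "\n")
  invisible(x)
}
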