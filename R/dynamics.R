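#' Pairwise stage comparisons per feature element
#'
#' Two-sided two-sample Student t-tests (pooled variance) on log-cpm
#' replicates, per element, for each requested stage pair; p < 0.01 is
#' flagged significant by default. The per-pair mean log-cpm and log
#' fold change support MA-style comparison plots. Degenerate cases (zero
#' variance in both groups) give p = 1 when the means are equal and p = 0,
#' flagged, when they differ.
#'
#' @param norm A [cpm_normalize()] result.
#' @param pairs Two-column matrix or list of stage pairs; defaults to all
#'   consecutive stage pairs in chronological order.
#' @param alpha Significance threshold (default 0.01).
#' @return A `medip_pairwise` tibble: element_id, stage_a, stage_b,
#'   mean_log_cpm, log_fc, t, df, p_value, significant, degenerate.
#' @export
pairwise_stage_tests <- function(norm, pairs = NULL, alpha = 0.01) {
  stages <- medip_stages()
  stages <- stages[stages %in% norm$samples$stage]
  if (is.null(pairs)) {
    pairs <- cbind(head(stages, -1), stages[-1])
  }
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  lc <- tbl_to_matrix(norm$log_cpm)
  stage_of <- norm$samples$stage[match(colnames(lc), norm$samples$sample_id)]
  out <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    a <- lc[, stage_of == pairs[i, 1], drop = FALSE]
    b <- lc[, stage_of == pairs[i, 2], drop = FALSE]
    tt <- row_student_t(a, b)
    out[[i]] <- tibble(
      element_id = rownames(lc),
      stage_a = pairs[i, 1], stage_b = pairs[i, 2],
      mean_log_cpm = unname((rowMeans(a) + rowMeans(b)) / 2),
      log_fc = unname(rowMeans(b) - rowMeans(a)),
      t = unname(tt$t), df = unname(tt$df), p_value = unname(tt$p),
      significant = unname(tt$p < alpha),
      degenerate = unname(tt$degenerate)
    )
  }
  structure(bind_rows(out), class = c("medip_pairwise", class(tibble())))
}

# vectorised pooled-variance two-sample Student t across matrix rows
row_student_t <- function(a, b) {
  n_a <- ncol(a); n_b <- ncol(b)
  if (n_a < 2 || n_b < 2) abort("need >= 2 replicates per group")
  m_a <- rowMeans(a); m_b <- rowMeans(b)
  v_a <- rowSums((a - m_a)^2) / (n_a - 1)
  v_b <- rowSums((b - m_b)^2) / (n_b - 1)
  df <- n_a + n_b - 2
  sp2 <- ((n_a - 1) * v_a + (n_b - 1) * v_b) / df
  se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
  t <- (m_a - m_b) / se
  p <- 2 * pt(-abs(t), df)
  degenerate <- se == 0
  t[degenerate & m_a == m_b] <- 0
  p[degenerate & m_a == m_b] <- 1
  p[degenerate & m_a != m_b] <- 0
  list(t = t, df = rep(df, length(t)), p = p, degenerate = degenerate)
}

#' Select genes with dynamic CDS methylation across stages
#'
#' Per gene, a one-way ANOVA of normalised CDS methylation (gene-level
#' log-cpm, averaged over the gene's CDS elements) against the
#' developmental stages; genes with ANOVA p below `alpha` are flagged
#' dynamic. Bonferroni-adjusted post-hoc pairwise stage contrasts are
#' computed for the dynamic genes. Genes with all-zero counts are skipped
#' and tallied.
#'
#' @param norm A [cpm_normalize()] result.
#' @param annotation A [medip_annotation()].
#' @param alpha Selection threshold on the ANOVA p-value (default 0.01;
#'   0.0001 is the stricter clustering-grade choice).
#' @param posthoc_alpha Significance level for the Bonferroni-adjusted
#'   post-hoc contrasts (default 0.01).
#' @param posthoc Whether to run the post-hoc contrasts.
#' @return A `medip_dynamics` object: `genes` (gene_id, anova_f, anova_p,
#'   dynamic), `profiles` (stage-mean cpm per gene), `posthoc`, and
#'   `n_skipped`.
#' @export
anova_dynamic_selection <- function(norm, annotation, alpha = 0.01,
                                    posthoc_alpha = 0.01, posthoc = TRUE) {
  cpm <- tbl_to_matrix(norm$cpm)
  el <- annotation$elements
  cds <- el[el$feature_class == "CDS" & !is.na(el$gene_id), ]
  idx <- match(cds$element_id, rownames(cpm))
  keep <- !is.na(idx)
  gene_cpm <- rowsum(cpm[idx[keep], , drop = FALSE], cds$gene_id[keep])
  gene_cpm <- gene_cpm / as.vector(table(cds$gene_id[keep])[rownames(gene_cpm)])

  zero <- rowSums(gene_cpm) == 0
  n_skipped <- sum(zero)
  gene_cpm <- gene_cpm[!zero, , drop = FALSE]
  gene_log <- log2(gene_cpm + 0.25)

  stage_of <- factor(
    norm$samples$stage[match(colnames(gene_cpm), norm$samples$sample_id)],
    levels = medip_stages()
  )
  stage_of <- droplevels(stage_of)

  fp <- t(apply(gene_log, 1, function(y) {
    ht <- tryCatch(oneway.test(y ~ stage_of, var.equal = TRUE),
                   error = function(e) NULL)
    if (is.null(ht) || is.na(ht$p.value)) c(NA_real_, NA_real_) else
      c(unname(ht$statistic), ht$p.value)
  }))
  genes <- tibble(gene_id = rownames(gene_log), anova_f = unname(fp[, 1]),
                  anova_p = unname(fp[, 2]),
                  dynamic = unname(!is.na(fp[, 2]) & fp[, 2] < alpha))

  # stage-mean cpm profiles (kinetics vectors)
  profiles <- sapply(levels(stage_of), function(st) {
    rowMeans(gene_cpm[, stage_of == st, drop = FALSE])
  })

  ph <- NULL
  if (posthoc && any(genes$dynamic)) {
    dyn <- genes$gene_id[genes$dynamic]
    ph <- purrr::map_dfr(dyn, function(g) {
      pw <- suppressWarnings(
        pairwise.t.test(gene_log[g, ], stage_of,
                        p.adjust.method = "bonferroni", pool.sd = TRUE)
      )
      as_tibble(as.table(pw$p.value), .name_repair = "minimal") |>
        setNames(c("stage_a", "stage_b", "p_adj")) |>
        filter(!is.na(.data$p_adj)) |>
        mutate(gene_id = g, significant = .data$p_adj < posthoc_alpha)
    })
  }
  structure(list(genes = genes, profiles = matrix_to_tbl(profiles, "gene_id"),
                 posthoc = ph, n_skipped = n_skipped, alpha = alpha),
            class = c("medip_dynamics", "list"))
}

#' @export
print.medip_dynamics <- function(x, ...) {
  cat(sprintf("<medip_dynamics> %d genes tested, %d dynamic (alpha %.2g), %d skipped\n",
              nrow(x$genes), sum(x$genes$dynamic), x$alpha, x$n_skipped))
  invisible(x)
}

#' K-means clustering of methylation kinetics
#'
#' Clusters the stage-ordered methylation profiles of the dynamic genes.
#' Profiles are z-scored across stages first, so clusters capture the
#' shape of the kinetics, not the methylation level. K-means uses
#' Euclidean distance with the best of `restarts` random initialisations,
#' deterministic under the seed.
#'
#' @param dynamics A [anova_dynamic_selection()] result, or a tibble of
#'   profiles (`gene_id` + stage columns).
#' @param k Number of clusters (default 5).
#' @param seed Integer seed.
#' @param restarts Random restarts (default 25).
#' @param dynamic_only Cluster only genes flagged dynamic (when `dynamics`
#'   is a `medip_dynamics`).
#' @return A `medip_clusters` object: `assignments` (gene_id, cluster),
#'   `centroids` (cluster x stage, z-score units), `tot_withinss`.
#' @export
cluster_kinetics <- function(dynamics, k = 5, seed = 1L, restarts = 25,
                             dynamic_only = TRUE) {
  profiles <- if (inherits(dynamics, "medip_dynamics")) {
    pr <- dynamics$profiles
    if (dynamic_only) {
      pr[pr$gene_id %in% dynamics$genes$gene_id[dynamics$genes$dynamic], ]
    } else pr
  } else {
    as_tibble(dynamics)
  }
  m <- tbl_to_matrix(profiles)
  sds <- apply(m, 1, sd)
  m <- m[sds > 0, , drop = FALSE]
  z <- t(scale(t(m)))
  if (nrow(z) < k) {
    abort(sprintf("only %d usable profiles for k = %d clusters", nrow(z), k))
  }
  km <- with_substream(seed, "kmeans", {
    kmeans(z, centers = k, nstart = restarts, iter.max = 50)
  })
  structure(list(
    assignments = tibble(gene_id = rownames(z),
                         cluster = unname(km$cluster)),
    centroids = matrix_to_tbl(km$centers, "cluster") |>
      mutate(cluster = seq_len(k)),
    tot_withinss = km$tot.withinss,
    k = k
  ), class = c("medip_clusters", "list"))
}

#' @export
print.medip_clusters <- function(x, ...) {
  cat(sprintf("<medip_clusters> k = %d, %d genes, total within-SS %.2f\n",
              x$k, nrow(x$assignments), x$tot_withinss))
  invisible(x)
}

#' Physical methylation map of a scaffold
#'
#' Per-stage normalised methylation signal in non-overlapping windows
#' (default 10 kb) tiling a scaffold: window counts are cpm-normalised per
#' sample and averaged across the replicates of each stage (or of each
#' pooled stage group, e.g. the mid-larval stages for the four-phase view).
#'
#' @param bins A [bin_fragments()] result covering the scaffold.
#' @param samples Sample sheet with `sample_id`, `stage`, `library_size`.
#' @param scaffold Scaffold name.
#' @param width Window width in bp (default 10000); a width larger than
#'   the scaffold yields a single window.
#' @param pool Optional named list mapping a track label to the stages
#'   averaged into it; defaults to one track per stage.
#' @return A `medip_physical_map` tibble: scaffold, start, end, stage,
#'   value (mean cpm).
#' @export
physical_map <- function(bins, samples, scaffold, width = 10000,
                         pool = NULL) {
  if (!scaffold %in% names(bins$counts)) abort("scaffold not in bins")
  m <- bins$counts[[scaffold]]
  sc_len <- bins$scaffolds$length[bins$scaffolds$scaffold == scaffold]
  bw <- bins$binwidth
  k <- max(1L, width %/% bw)
  win_of_bin <- (seq_len(nrow(m)) - 1L) %/% k
  agg <- rowsum(m, win_of_bin)
  lib <- samples$library_size[match(colnames(m), samples$sample_id)]
  cpm <- sweep(agg, 2, lib, "/") * 1e6
  stage_of <- samples$stage[match(colnames(m), samples$sample_id)]
  if (is.null(pool)) {
    pool <- setNames(as.list(unique(stage_of)), unique(stage_of))
  }
  win_idx <- as.integer(rownames(agg))
  out <- purrr::imap_dfr(pool, function(stages, label) {
    cols <- stage_of %in% stages
    tibble(
      scaffold = scaffold,
      start = win_idx * k * bw,
      end = pmin(sc_len, (win_idx + 1L) * k * bw),
      stage = label,
      value = rowMeans(cpm[, cols, drop = FALSE])
    )
  })
  structure(out, class = c("medip_physical_map", class(tibble())))
}

#' Persistence of gene methylation between two stages
#'
#' The fraction of genes methylated at the later stage that were already
#' methylated at the earlier stage, with the complementary de novo gene
#' list.
#'
#' @param calls A [call_methylated()] result with gene-level calls.
#' @param earlier,later Stage labels (defaults: oocyte, spat).
#' @return List: `fraction`, `n_later`, `persistent_genes`,
#'   `de_novo_genes`.
#' @export
persistence <- function(calls, earlier = "oocyte", later = "spat") {
  if (is.null(calls$genes)) abort("gene-level calls required (pass an annotation to call_methylated)")
  g <- calls$genes
  if (!all(c(earlier, later) %in% names(g))) abort("stage not in calls")
  later_set <- g$gene_id[g[[later]]]
  if (!length(later_set)) {
    warn(sprintf("no genes methylated at %s; persistence undefined", later))
    return(list(fraction = NA_real_, n_later = 0L,
                persistent_genes = character(), de_novo_genes = character()))
  }
  earlier_set <- g$gene_id[g[[earlier]]]
  persistent <- intersect(later_set, earlier_set)
  list(
    fraction = length(persistent) / length(later_set),
    n_later = length(later_set),
    persistent_genes = persistent,
    de_novo_genes = setdiff(later_set, earlier_set)
  )
}
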