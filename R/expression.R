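#' Expression of methylated vs unmethylated genes
#'
#' Summarises gene expression (mean across stages) separately for genes
#' called methylated (at any stage) and unmethylated, and tests the
#' location difference with a two-sided Wilcoxon rank-sum test.
#'
#' @param calls A [call_methylated()] result with gene-level calls.
#' @param expression Tibble: `gene_id` plus one expression column per
#'   stage.
#' @return List: `summary` (per group n, median, q25, q75) and `p_value`.
#' @export
expression_by_methylation_status <- function(calls, expression) {
  if (is.null(calls$genes)) abort("gene-level calls required")
  g <- calls$genes
  meth_any <- rowSums(as.matrix(g[, -1])) > 0
  status <- tibble(gene_id = g$gene_id,
                   methylated = meth_any)
  expr <- tibble(gene_id = expression$gene_id,
                 expression = rowMeans(as.matrix(expression[, -1])))
  d <- inner_join(status, expr, by = "gene_id")
  if (!any(d$methylated) || !any(!d$methylated)) {
    abort("both methylated and unmethylated genes are required")
  }
  summary <- d |>
    group_by(.data$methylated) |>
    summarise(n = n(), median = median(.data$expression),
              q25 = quantile(.data$expression, 0.25),
              q75 = quantile(.data$expression, 0.75), .groups = "drop")
  p <- suppressWarnings(
    wilcox.test(expression ~ methylated, data = d)$p.value
  )
  list(summary = summary, p_value = p)
}

# stable decile assignment: ties broken by gene id order, sizes differ <= 1
assign_deciles <- function(x, ids, n_bins = 10) {
  ord <- order(x, ids)
  sizes <- rep(length(x) %/% n_bins, n_bins)
  extra <- length(x) %% n_bins
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  dec <- integer(length(x))
  dec[ord] <- rep(seq_len(n_bins), times = sizes)
  dec
}

#' Decile trends of methylation against expression level and variability
#'
#' Bins genes into deciles of mean expression and of expression
#' variability (coefficient of variation across stages, with a floor of
#' 0.01 on the mean), and reports the mean CDS methylation per decile with
#' a Spearman monotonicity statistic over the decile means.
#'
#' @param methylation Tibble `gene_id`, `methylation` (e.g. mean CDS cpm
#'   across stages); typically the methylated genes only.
#' @param expression Tibble `gene_id` plus stage columns.
#' @return A `medip_deciles` list: `by_level`, `by_cv` (decile tibbles) and
#'   `stats` (Spearman rho of decile index vs mean methylation).
#' @export
decile_trends <- function(methylation, expression) {
  expr_m <- as.matrix(expression[, -1])
  d <- tibble(
    gene_id = expression$gene_id,
    expr_mean = rowMeans(expr_m),
    expr_cv = apply(expr_m, 1, sd) / pmax(rowMeans(expr_m), 0.01)
  ) |>
    inner_join(methylation, by = "gene_id")
  if (nrow(d) < 10) abort("need at least 10 genes for decile analysis")
  d$dec_level <- assign_deciles(d$expr_mean, d$gene_id)
  d$dec_cv <- assign_deciles(d$expr_cv, d$gene_id)
  by_level <- d |>
    group_by(decile = .data$dec_level) |>
    summarise(n = n(), mean_expression = mean(.data$expr_mean),
              mean_methylation = mean(.data$methylation), .groups = "drop")
  by_cv <- d |>
    group_by(decile = .data$dec_cv) |>
    summarise(n = n(), mean_expression_cv = mean(.data$expr_cv),
              mean_methylation = mean(.data$methylation), .groups = "drop")
  stats <- tibble(
    axis = c("expression_level", "expression_cv"),
    spearman_rho = c(
      suppressWarnings(cor(by_level$decile, by_level$mean_methylation,
                           method = "spearman")),
      suppressWarnings(cor(by_cv$decile, by_cv$mean_methylation,
                           method = "spearman"))
    )
  )
  structure(list(by_level = by_level, by_cv = by_cv, stats = stats,
                 genes = d),
            class = c("medip_deciles", "list"))
}

#' In-gene methylation pattern vs expression
#'
#' Bins genes by the skew of their gene-body methylation pattern (mean
#' absolute log2 INT/CDS ratio across stages: balanced, intermediate,
#' skewed terciles), runs a one-way ANOVA of log expression across the
#' bins, and correlates pattern variability (ratio CV across stages) with
#' expression variability (CV across stages). Genes with undefined ratios
#' are excluded and tallied.
#'
#' @param pattern A [gbm_pattern_ratio()] result.
#' @param expression Tibble `gene_id` plus stage columns.
#' @return List: `anova` (F, p), `correlation` (r, p), `bins` (per-bin
#'   expression summary), `n_excluded`.
#' @export
pattern_vs_expression <- function(pattern, expression) {
  stage_cols <- setdiff(names(pattern), c("gene_id", "pattern_cv"))
  ratios <- as.matrix(pattern[, stage_cols])
  skew <- apply(ratios, 1, function(r) {
    r <- r[is.finite(r) & r > 0]
    if (!length(r)) NA_real_ else mean(abs(log2(r)))
  })
  expr_m <- as.matrix(expression[, -1])
  expr <- tibble(
    gene_id = expression$gene_id,
    expr_mean = rowMeans(expr_m),
    expr_cv = apply(expr_m, 1, sd) / pmax(rowMeans(expr_m), 0.01)
  )
  d <- tibble(gene_id = pattern$gene_id, skew = skew,
              pattern_cv = pattern$pattern_cv) |>
    inner_join(expr, by = "gene_id")
  n_all <- nrow(d)
  d <- d[is.finite(d$skew), ]
  n_excluded <- n_all - nrow(d)
  if (nrow(d) < 9) abort("too few genes with defined pattern ratios")
  br <- unique(quantile(d$skew, c(1 / 3, 2 / 3)))
  if (length(br) < 2 || diff(range(d$skew)) == 0) {
    # degenerate: all patterns equally balanced, one bin
    d$bin <- factor(rep("balanced", nrow(d)),
                    levels = c("balanced", "intermediate", "skewed"))
  } else {
    d$bin <- cut(d$skew, c(-Inf, br, Inf),
                 labels = c("balanced", "intermediate", "skewed"))
  }
  log_expr <- log2(d$expr_mean + 0.01)
  anova <- if (stats::var(log_expr) == 0 || length(unique(d$bin)) < 2) {
    tibble(f = 0, p_value = 1)
  } else {
    ht <- oneway.test(log_expr ~ d$bin, var.equal = TRUE)
    tibble(f = unname(ht$statistic), p_value = ht$p.value)
  }
  ok <- is.finite(d$pattern_cv)
  correlation <- if (sum(ok) >= 3 && sd(d$pattern_cv[ok]) > 0 &&
                     sd(d$expr_cv[ok]) > 0) {
    ct <- cor.test(d$pattern_cv[ok], d$expr_cv[ok])
    tibble(r = unname(ct$estimate), p_value = ct$p.value)
  } else {
    tibble(r = NA_real_, p_value = NA_real_)
  }
  bins <- d |>
    group_by(.data$bin) |>
    summarise(n = n(), mean_expression = mean(.data$expr_mean),
              .groups = "drop")
  list(anova = anova, correlation = correlation, bins = bins,
       n_excluded = n_excluded)
}

#' Correlation of methylation and expression kinetics per gene
#'
#' Pearson correlation between each gene's stage-ordered methylation
#' kinetics and its expression kinetics; a gene is called coupled when
#' r > 0 and p < `alpha` (the direction requirement makes the call
#' meaningful — r-squared alone is almost surely positive). Genes with a
#' constant vector are excluded and tallied.
#'
#' @param profiles Tibble `gene_id` plus stage columns of methylation
#'   kinetics (e.g. `anova_dynamic_selection()$profiles`, subset to the
#'   dynamic genes).
#' @param expression Tibble `gene_id` plus stage columns.
#' @param alpha Coupling significance threshold (default 0.05).
#' @return A `medip_kinetics_cor` tibble: gene_id, r, r2, p_value,
#'   coupled; attributes `coupled_fraction`, `n_tested`, `n_excluded`.
#' @export
kinetics_correlation <- function(profiles, expression, alpha = 0.05) {
  stages <- intersect(names(profiles)[-1], names(expression)[-1])
  if (length(stages) < 3) abort("kinetics vectors need >= 3 shared stages")
  mm <- tbl_to_matrix(profiles[, c("gene_id", stages)])
  em <- tbl_to_matrix(expression[, c("gene_id", stages)])
  common <- intersect(rownames(mm), rownames(em))
  mm <- mm[common, , drop = FALSE]
  em <- em[common, , drop = FALSE]
  const <- apply(mm, 1, sd) == 0 | apply(em, 1, sd) == 0
  res <- purrr::map_dfr(which(!const), function(i) {
    ct <- cor.test(mm[i, ], em[i, ])
    tibble(gene_id = common[i], r = unname(ct$estimate),
           r2 = unname(ct$estimate)^2, p_value = ct$p.value)
  })
  if (!nrow(res)) {
    res <- tibble(gene_id = character(), r = numeric(), r2 = numeric(),
                  p_value = numeric())
  }
  res$coupled <- res$r > 0 & res$p_value < alpha
  out <- structure(res, class = c("medip_kinetics_cor", class(tibble())))
  attr(out, "coupled_fraction") <- if (nrow(res)) mean(res$coupled) else NA_real_
  attr(out, "n_tested") <- nrow(res)
  attr(out, "n_excluded") <- sum(const)
  out
}

#' DMR proximity and expression variability
#'
#' For each gene and step, the signed distance from the gene's
#' transcription start site to the nearest DMR centre on the same scaffold
#' (negative = upstream, respecting gene strand), whether the gene is
#' DMR-associated (|distance| within `radius`), and the gene's expression
#' log fold change over that step. Compares the fold-change dispersion of
#' associated vs unassociated genes and correlates DMR methylation change
#' with gene expression change.
#'
#' @param dmrs DMR tibble (`step`, `scaffold`, `center`, `log2fc`).
#' @param annotation A [medip_annotation()].
#' @param expression Tibble `gene_id` plus stage columns.
#' @param radius Association radius in bp (default 1e5).
#' @param expr_floor Floor added to stage means before the expression log
#'   fold change.
#' @return List: `genes` (per gene x step tibble), `dispersion` (per step
#'   sd of |lfc| in each group), `correlation` (per step, DMR log2fc vs
#'   expression lfc among associated genes).
#' @export
dmr_proximity_expression <- function(dmrs, annotation, expression,
                                     radius = 1e5, expr_floor = 0.01) {
  genes <- gene_table(annotation)
  steps <- sort(unique(dmrs$step))
  if (!length(steps)) {
    warn("no DMRs; all genes unassociated, comparison skipped")
    return(list(genes = tibble(), dispersion = tibble(),
                correlation = tibble()))
  }
  em <- as.matrix(expression[, -1])
  rownames(em) <- expression$gene_id
  stage_lfc <- function(design) {
    e0 <- rowMeans(em[, design$earlier, drop = FALSE])
    e1 <- rowMeans(em[, design$later, drop = FALSE])
    log2((e1 + expr_floor) / (e0 + expr_floor))
  }
  rows <- vector("list", length(steps))
  for (k in seq_along(steps)) {
    design <- step_design(steps[k])
    lfc <- stage_lfc(design)
    d_step <- dmrs[dmrs$step == steps[k], ]
    signed <- rep(NA_real_, nrow(genes))
    dmr_lfc <- rep(NA_real_, nrow(genes))
    for (i in seq_len(nrow(genes))) {
      cen <- d_step$center[d_step$scaffold == genes$scaffold[i]]
      if (!length(cen)) next
      delta <- cen - genes$tss[i]
      j <- which.min(abs(delta))
      signed[i] <- if (genes$strand[i] == "-") -delta[j] else delta[j]
      dmr_lfc[i] <- d_step$log2fc[d_step$scaffold == genes$scaffold[i]][j]
    }
    rows[[k]] <- tibble(
      gene_id = genes$gene_id, step = steps[k],
      signed_distance = signed,
      associated = !is.na(signed) & abs(signed) <= radius,
      expr_lfc = unname(lfc[genes$gene_id]),
      dmr_log2fc = dmr_lfc
    )
  }
  gtab <- bind_rows(rows)
  dispersion <- gtab |>
    group_by(.data$step, .data$associated) |>
    summarise(n = n(), sd_abs_lfc = sd(abs(.data$expr_lfc), na.rm = TRUE),
              .groups = "drop")
  correlation <- gtab |>
    filter(.data$associated, !is.na(.data$expr_lfc)) |>
    group_by(.data$step) |>
    summarise(
      n = n(),
      r = if (n() >= 3 && sd(.data$dmr_log2fc) > 0 &&
              sd(.data$expr_lfc) > 0) {
        cor(.data$dmr_log2fc, .data$expr_lfc)
      } else NA_real_,
      .groups = "drop"
    )
  list(genes = gtab, dispersion = dispersion, correlation = correlation)
}
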