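#' Counts-per-million normalisation
#'
#' The methylation level of a feature element is its fragment count per
#' million library fragments: `cpm = count / library_size * 1e6`. A log
#' scale (`log2(cpm + 0.25)`, quarter-count pseudocount) is carried
#' alongside for display, t-tests and clustering; statistical tests on
#' proportions use the raw counts, which are retained in the returned
#' object.
#'
#' @param counts A [medip_counts()].
#' @return A `medip_norm` object: list with `cpm`, `log_cpm`, `counts`
#'   (tibbles, `element_id` plus sample columns) and `samples`.
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 20, seed = 1)
#' cm <- simulate_counts(simulate_truth(simulate_annotation(cfg), cfg),
#'                       simulate_annotation(cfg), cfg)
#' norm <- cpm_normalize(cm)
#' norm$cpm[1:3, 1:3]
cpm_normalize <- function(counts) {
  if (any(counts$samples$library_size <= 0)) {
    abort("library sizes must be positive")
  }
  m <- counts_matrix(counts)
  cpm <- sweep(m, 2, counts$samples$library_size, "/") * 1e6
  structure(list(
    cpm = matrix_to_tbl(cpm, "element_id"),
    log_cpm = matrix_to_tbl(log2(cpm + 0.25), "element_id"),
    counts = counts$counts,
    samples = counts$samples
  ), class = c("medip_norm", "list"))
}

#' @export
print.medip_norm <- function(x, ...) {
  cat(sprintf("<medip_norm> %d elements x %d samples (cpm, log2 cpm + 0.25)\n",
              nrow(x$cpm), nrow(x$samples)))
  invisible(x)
}

#' Call feature elements (and genes) methylated per stage
#'
#' An element is called methylated at a stage when at least `min_replicates`
#' biological replicates of that stage have at least `min_cpm` (inclusive)
#' counts per million. A gene is called methylated when any of its CDS or
#' intron elements is. The call is monotone: raising any replicate's cpm
#' never unmakes a call.
#'
#' @param norm A [cpm_normalize()] result.
#' @param annotation Optional [medip_annotation()]; needed for gene-level
#'   calls.
#' @param min_cpm Call threshold in cpm (default 1).
#' @param min_replicates Minimum replicates at or above threshold (default 2).
#' @return A `medip_calls` object: `elements` and (if annotation given)
#'   `genes` logical tibbles with one column per stage, and `stage_tally`.
#' @export
call_methylated <- function(norm, annotation = NULL, min_cpm = 1,
                            min_replicates = 2) {
  samples <- norm$samples
  stages <- medip_stages()
  stages <- stages[stages %in% samples$stage]
  n_rep <- table(factor(samples$stage, levels = stages))
  low <- names(n_rep)[n_rep < min_replicates]
  if (length(low)) {
    abort(sprintf("stage(s) with fewer than %d replicates: %s",
                  min_replicates, paste(low, collapse = ", ")))
  }
  cpm <- tbl_to_matrix(norm$cpm)
  calls <- sapply(stages, function(st) {
    cols <- samples$sample_id[samples$stage == st]
    rowSums(cpm[, cols, drop = FALSE] >= min_cpm) >= min_replicates
  })
  rownames(calls) <- rownames(cpm)

  genes <- NULL
  if (!is.null(annotation)) {
    el <- annotation$elements
    body <- el[el$feature_class %in% c("CDS", "INT") & !is.na(el$gene_id), ]
    idx <- match(body$element_id, rownames(calls))
    keep <- !is.na(idx)
    gcalls <- rowsum((calls[idx[keep], , drop = FALSE]) * 1L,
                     body$gene_id[keep]) > 0
    genes <- matrix_to_tbl(gcalls, "gene_id")
  }
  tally <- tibble(
    stage = stages,
    methylated = unname(colSums(calls)),
    unmethylated = unname(colSums(!calls))
  )
  structure(list(
    elements = matrix_to_tbl(calls, "element_id"),
    genes = genes,
    stage_tally = tally,
    params = list(min_cpm = min_cpm, min_replicates = min_replicates)
  ), class = c("medip_calls", "list"))
}

#' @export
print.medip_calls <- function(x, ...) {
  cat("<medip_calls>\n")
  print(x$stage_tally)
  invisible(x)
}

#' Distribution of methylation across feature classes and stages
#'
#' For each stage, the proportion of the total assigned methylation signal
#' (stage-mean cpm) in each feature class, plus a Pearson chi-square test
#' of independence of the feature-class x stage table built from the raw
#' counts.
#'
#' @param norm A [cpm_normalize()] result (retains raw counts).
#' @param annotation A [medip_annotation()].
#' @return List: `proportions` (tibble stage x feature_class, proportions
#'   summing to 1 per stage), `table` (class x stage raw-count matrix) and
#'   `chisq` (tidy one-row tibble).
#' @export
methylation_distribution <- function(norm, annotation) {
  el <- annotation$elements
  cls <- el$feature_class[match(norm$cpm$element_id, el$element_id)]
  if (anyNA(cls)) abort("normalised matrix has elements missing from the annotation")
  classes <- c("CDS", "INT", "PRO", "REP", "TE")
  stages <- unique(norm$samples$stage)

  cpm <- tbl_to_matrix(norm$cpm)
  cnt <- tbl_to_matrix(norm$counts)
  stage_of <- norm$samples$stage[match(colnames(cpm), norm$samples$sample_id)]

  stage_cpm <- sapply(stages, function(st) {
    rowMeans(cpm[, stage_of == st, drop = FALSE])
  })
  by_class_cpm <- rowsum(stage_cpm, cls)
  missing_cls <- setdiff(classes, rownames(by_class_cpm))
  if (length(missing_cls)) {
    warn(paste("no elements of class:", paste(missing_cls, collapse = ", ")))
    add <- matrix(0, length(missing_cls), ncol(by_class_cpm),
                  dimnames = list(missing_cls, colnames(by_class_cpm)))
    by_class_cpm <- rbind(by_class_cpm, add)
  }
  by_class_cpm <- by_class_cpm[classes, , drop = FALSE]
  props <- sweep(by_class_cpm, 2, colSums(by_class_cpm), "/")

  stage_cnt <- sapply(stages, function(st) {
    rowSums(cnt[, stage_of == st, drop = FALSE])
  })
  tab <- rowsum(stage_cnt, cls)
  tab <- tab[intersect(classes, rownames(tab)), , drop = FALSE]
  chisq <- chi_square_independence(tab)

  proportions <- as_tibble(props, rownames = "feature_class") |>
    tidyr::pivot_longer(-"feature_class", names_to = "stage",
                        values_to = "proportion")
  list(proportions = proportions, table = tab, chisq = chisq)
}

#' In-gene methylation pattern: length-normalised INT/CDS ratio
#'
#' For each gene and stage, the ratio of intron to exon methylation after
#' normalising each for total element length:
#' `(sum INT cpm / sum INT bp) / (sum CDS cpm / sum CDS bp)`, using
#' stage-mean cpm. A gene-level pattern-variability statistic (the
#' coefficient of variation of the ratio across stages) accompanies the
#' ratios. Stages with zero CDS methylation give a missing ratio (never
#' infinity).
#'
#' @param norm A [cpm_normalize()] result.
#' @param annotation A [medip_annotation()].
#' @return Tibble: `gene_id`, one ratio column per stage, `pattern_cv`.
#' @export
gbm_pattern_ratio <- function(norm, annotation) {
  el <- annotation$elements
  body <- el[el$feature_class %in% c("CDS", "INT") & !is.na(el$gene_id), ]
  body$len <- body$end - body$start
  cpm <- tbl_to_matrix(norm$cpm)
  idx <- match(body$element_id, rownames(cpm))
  body <- body[!is.na(idx), ]
  idx <- idx[!is.na(idx)]
  stage_of <- norm$samples$stage[match(colnames(cpm), norm$samples$sample_id)]
  stages <- medip_stages()
  stages <- stages[stages %in% stage_of]
  stage_cpm <- sapply(stages, function(st) {
    rowMeans(cpm[idx, stage_of == st, drop = FALSE])
  })

  key <- paste(body$gene_id, body$feature_class, sep = ".")
  sum_cpm <- rowsum(stage_cpm, key)
  sum_len <- rowsum(body$len, key)

  genes <- sort(unique(body$gene_id))
  get_density <- function(cls) {
    k <- paste(genes, cls, sep = ".")
    num <- matrix(NA_real_, length(genes), length(stages),
                  dimnames = list(genes, stages))
    hit <- k %in% rownames(sum_cpm)
    num[hit, ] <- sum_cpm[k[hit], , drop = FALSE] /
      sum_len[k[hit], 1L]
    num
  }
  int_d <- get_density("INT")
  cds_d <- get_density("CDS")
  ratio <- int_d / cds_d
  ratio[!is.finite(ratio)] <- NA_real_
  # a gene needs both CDS and INT parts for the pattern to be defined
  has_both <- rowSums(!is.na(int_d)) > 0 & rowSums(!is.na(cds_d)) > 0
  ratio <- ratio[has_both, , drop = FALSE]
  cv <- apply(ratio, 1, function(r) {
    r <- r[is.finite(r)]
    if (length(r) < 2 || mean(r) == 0) NA_real_ else sd(r) / mean(r)
  })
  out <- matrix_to_tbl(ratio, "gene_id")
  out$pattern_cv <- unname(cv)
  out
}

#' Pearson chi-square test of independence
#'
#' Pearson's statistic on an r x c contingency table, without continuity
#' correction, with `df = (r-1)(c-1)` and an upper-tail chi-square p-value.
#'
#' @param table Numeric matrix (or object coercible to one) of counts.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi_square_independence(rbind(c(122, 81), c(121, 63), c(64150, 21263)))
chi_square_independence <- function(table) {
  m <- as.matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    abort("contingency table has a zero marginal")
  }
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  tibble(statistic = unname(ht$statistic), df = unname(ht$parameter),
         p_value = unname(ht$p.value))
}
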