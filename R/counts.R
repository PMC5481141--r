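#' Feature count matrix container
#'
#' Integer MeDIP fragment counts per feature element per sample, together
#' with the sample sheet. `library_size` is the per-sample denominator used
#' for cpm normalisation and must be at least the column sum of the counts.
#'
#' @param counts Tibble: `element_id` column then one integer column per
#'   sample.
#' @param samples Tibble with `sample_id`, `stage`, `replicate`,
#'   `library_size`; sample ids must match the count columns.
#' @return A `medip_counts` object.
#' @export
medip_counts <- function(counts, samples) {
  counts <- as_tibble(counts)
  samples <- as_tibble(samples)
  stopifnot(names(counts)[1] == "element_id")
  if (!setequal(names(counts)[-1], samples$sample_id)) {
    abort("count columns and sample sheet disagree")
  }
  counts <- counts[, c("element_id", samples$sample_id)]
  m <- tbl_to_matrix(counts)
  if (any(m < 0) || any(m != round(m))) {
    abort("counts must be non-negative integers")
  }
  if (!all(samples$stage %in% medip_stages())) {
    abort("sample stages must come from the 8-stage vocabulary")
  }
  if (any(samples$library_size < colSums(m))) {
    abort("library_size must be >= the sample's total feature count")
  }
  structure(list(counts = counts, samples = samples),
            class = c("medip_counts", "list"))
}

#' @export
print.medip_counts <- function(x, ...) {
  cat(sprintf("<medip_counts> %d elements x %d samples (%d stages)\n",
              nrow(x$counts), nrow(x$samples), length(unique(x$samples$stage))))
  invisible(x)
}

counts_matrix <- function(x) tbl_to_matrix(x$counts)
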