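#' Genome annotation container
#'
#' Holds scaffolds and located feature elements of the five classes used
#' throughout the pipeline: exons (`CDS`), introns (`INT`), promoters
#' (`PRO`), repeats (`REP`) and transposable elements (`TE`). Coordinates
#' are 0-based half-open internally; [read_annotation()] and
#' [write_annotation()] convert from/to the 1-based closed GFF3 convention
#' and the 0-based half-open BED convention.
#'
#' @param scaffolds Tibble with columns `scaffold`, `length`.
#' @param elements Tibble with columns `element_id`, `scaffold`, `start`,
#'   `end`, `feature_class`, `gene_id` (NA for REP/TE), `te_class`
#'   (`"I"`/`"II"`, NA for non-TE), `strand`.
#' @return A `medip_annotation` object.
#' @export
medip_annotation <- function(scaffolds, elements) {
  scaffolds <- as_tibble(scaffolds)
  elements <- as_tibble(elements)
  stopifnot(all(c("scaffold", "length") %in% names(scaffolds)))
  needed <- c("element_id", "scaffold", "start", "end", "feature_class",
              "gene_id", "te_class", "strand")
  stopifnot(all(needed %in% names(elements)))
  if (anyDuplicated(elements$element_id)) {
    abort("element ids must be unique")
  }
  bad_class <- setdiff(unique(elements$feature_class),
                       c("CDS", "INT", "PRO", "REP", "TE"))
  if (length(bad_class)) {
    abort(paste("unknown feature class:", paste(bad_class, collapse = ", ")))
  }
  len <- scaffolds$length[match(elements$scaffold, scaffolds$scaffold)]
  if (any(is.na(len))) abort("element on unknown scaffold")
  if (any(elements$start < 0 | elements$start >= elements$end |
          elements$end > len)) {
    abort("element coordinates must satisfy 0 <= start < end <= scaffold length")
  }
  gene_classes <- c("CDS", "INT", "PRO")
  if (any(elements$feature_class %in% gene_classes & is.na(elements$gene_id))) {
    abort("CDS/INT/PRO elements must carry a gene_id")
  }
  if (any(elements$feature_class == "TE" & is.na(elements$te_class))) {
    abort("TE elements must carry a te_class")
  }
  structure(list(scaffolds = scaffolds, elements = elements),
            class = c("medip_annotation", "list"))
}

#' @export
print.medip_annotation <- function(x, ...) {
  cat("<medip_annotation>\n")
  cat(sprintf("  %d scaffolds, %s bp total\n", nrow(x$scaffolds),
              format(sum(x$scaffolds$length), big.mark = ",")))
  tab <- table(x$elements$feature_class)
  cat("  elements:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "),
      "\n")
  invisible(x)
}

# element midpoints, used for mosaic membership and distance analyses
element_centers <- function(elements) {
  (elements$start + elements$end) / 2
}

# tibble of per-gene span and strand-aware TSS
gene_table <- function(annotation) {
  ge <- annotation$elements[!is.na(annotation$elements$gene_id) &
                              annotation$elements$feature_class %in%
                              c("CDS", "INT"), ]
  ge |>
    group_by(.data$gene_id, .data$scaffold, .data$strand) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    mutate(
      tss = ifelse(.data$strand == "-", .data$end, .data$start),
      center = (.data$start + .data$end) / 2
    )
}
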