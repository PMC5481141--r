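#' Read a genome annotation from GFF3 or BED
#'
#' Parses feature elements of the five classes (CDS, intron, promoter,
#' repeat, transposable element) into the package's internal 0-based
#' half-open representation. GFF3 coordinates (1-based closed) are
#' converted; BED coordinates are taken as-is. Promoters of length 100 bp
#' or shorter are dropped (only promoter sequences strictly longer than
#' 100 bp are retained), with the number dropped reported via a message.
#' Unknown feature types are skipped with a warning; duplicated element ids
#' are an error.
#'
#' @param path File path (`.gff3` or `.bed`).
#' @param format `"gff3"` or `"bed"`; guessed from the extension by default.
#' @return A [medip_annotation()].
#' @export
read_annotation <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed")
  if (format == "gff3") {
    type <- as.character(gr$type)
    class_map <- c(CDS = "CDS", intron = "INT", promoter = "PRO",
                   repeat_region = "REP", transposable_element = "TE")
    # scaffold extents are carried as 'region'/'gene' records, not elements
    keep_meta <- type %in% c("region", "gene")
    scaff <- tibble(
      scaffold = as.character(GenomicRanges::seqnames(gr)),
      end = GenomicRanges::end(gr), type = type
    ) |>
      group_by(.data$scaffold) |>
      summarise(length = max(.data$end), .groups = "drop")
    unknown <- !type %in% c(names(class_map), "region", "gene")
    if (any(unknown)) {
      warn(sprintf("skipping %d records of unknown feature type (%s)",
                   sum(unknown),
                   paste(unique(type[unknown]), collapse = ", ")))
    }
    el_gr <- gr[type %in% names(class_map)]
    elements <- tibble(
      element_id = as.character(el_gr$ID),
      scaffold = as.character(GenomicRanges::seqnames(el_gr)),
      start = GenomicRanges::start(el_gr) - 1L,
      end = GenomicRanges::end(el_gr),
      feature_class = unname(class_map[as.character(el_gr$type)]),
      gene_id = if (!is.null(el_gr$gene_id)) as.character(el_gr$gene_id) else NA_character_,
      te_class = if (!is.null(el_gr$te_class)) as.character(el_gr$te_class) else NA_character_,
      strand = as.character(GenomicRanges::strand(el_gr))
    )
    elements$strand[!elements$strand %in% c("+", "-")] <- "+"
  } else {
    # BED6 mirror: name encodes element_id|feature_class|gene_id|te_class
    parts <- strsplit(as.character(gr$name), "|", fixed = TRUE)
    elements <- tibble(
      element_id = vapply(parts, `[`, "", 1L),
      scaffold = as.character(GenomicRanges::seqnames(gr)),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr),
      feature_class = vapply(parts, `[`, "", 2L),
      gene_id = vapply(parts, `[`, "", 3L),
      te_class = vapply(parts, `[`, "", 4L),
      strand = as.character(GenomicRanges::strand(gr))
    )
    elements$gene_id[elements$gene_id %in% c("", ".")] <- NA_character_
    elements$te_class[elements$te_class %in% c("", ".")] <- NA_character_
    elements$strand[!elements$strand %in% c("+", "-")] <- "+"
    unknown <- !elements$feature_class %in% c("CDS", "INT", "PRO", "REP", "TE")
    if (any(unknown)) {
      warn(sprintf("skipping %d records of unknown feature type", sum(unknown)))
      elements <- elements[!unknown, ]
    }
    scaff <- elements |>
      group_by(.data$scaffold) |>
      summarise(length = max(.data$end), .groups = "drop")
  }
  if (anyDuplicated(elements$element_id)) {
    abort("annotation format error: duplicated element ids")
  }
  short_pro <- elements$feature_class == "PRO" &
    (elements$end - elements$start) <= 100
  if (any(short_pro)) {
    inform(sprintf("dropped %d promoter(s) of length <= 100 bp", sum(short_pro)))
    elements <- elements[!short_pro, ]
  }
  medip_annotation(scaff, elements)
}

#' Write a genome annotation to GFF3 or BED
#'
#' GFF3 output is 1-based closed with feature types
#' `CDS`/`intron`/`promoter`/`repeat_region`/`transposable_element`, the
#' TE class in a `te_class` attribute, and one `region` record per scaffold
#' carrying its length. BED6 output is 0-based half-open with the name
#' field encoding `element_id|feature_class|gene_id|te_class`.
#' `read_annotation(write_annotation(x))` round-trips coordinates (modulo
#' the promoter-length filter applied on read).
#'
#' @param annotation A [medip_annotation()].
#' @param path Output file path.
#' @param format `"gff3"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annotation, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  el <- annotation$elements
  if (format == "gff3") {
    class_map <- c(CDS = "CDS", INT = "intron", PRO = "promoter",
                   REP = "repeat_region", TE = "transposable_element")
    region <- GenomicRanges::GRanges(
      annotation$scaffolds$scaffold,
      IRanges::IRanges(1L, annotation$scaffolds$length),
      strand = "*", type = "region",
      ID = paste0("region_", annotation$scaffolds$scaffold)
    )
    gr <- GenomicRanges::GRanges(
      el$scaffold, IRanges::IRanges(el$start + 1L, el$end),
      strand = el$strand,
      type = unname(class_map[el$feature_class]),
      ID = el$element_id
    )
    gr$gene_id <- el$gene_id
    gr$te_class <- el$te_class
    region$gene_id <- NA_character_
    region$te_class <- NA_character_
    # rtracklayer warns about absent CDS phase; MeDIP features carry none
    suppressWarnings(rtracklayer::export(c(region, gr), path, format = "gff3"))
  } else {
    gr <- GenomicRanges::GRanges(
      el$scaffold, IRanges::IRanges(el$start + 1L, el$end),
      strand = el$strand
    )
    gr$name <- paste(el$element_id, el$feature_class,
                     ifelse(is.na(el$gene_id), ".", el$gene_id),
                     ifelse(is.na(el$te_class), ".", el$te_class),
                     sep = "|")
    gr$score <- 0L
    rtracklayer::export(gr, path, format = "bed")
  }
  invisible(path)
}

#' Read and write feature count matrices and sample sheets
#'
#' Counts are TSV with an `element_id` column then one integer column per
#' sample; the sample sheet is TSV with `sample_id`, `stage`, `replicate`,
#' `library_size`.
#'
#' @param counts_path,samples_path TSV file paths.
#' @return [read_counts()] returns a [medip_counts()].
#' @export
read_counts <- function(counts_path, samples_path) {
  counts <- readr::read_tsv(counts_path, show_col_types = FALSE)
  samples <- readr::read_tsv(samples_path, show_col_types = FALSE)
  medip_counts(counts, samples)
}

#' @rdname read_counts
#' @param x A [medip_counts()].
#' @export
write_counts <- function(x, counts_path, samples_path) {
  readr::write_tsv(x$counts, counts_path)
  readr::write_tsv(x$samples, samples_path)
  invisible(counts_path)
}

#' Write or read per-sample fragment BED files
#'
#' One BED3 file per sample (`<sample_id>.bed`) holding the 0-based
#' half-open fragment intervals.
#'
#' @param fragments Tibble with `sample_id`, `scaffold`, `start`, `end`.
#' @param dir Directory of per-sample BED files.
#' @return [read_fragments()] returns the combined fragments tibble.
#' @export
write_fragments <- function(fragments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in unique(fragments$sample_id)) {
    fr <- fragments[fragments$sample_id == sid, c("scaffold", "start", "end")]
    readr::write_tsv(fr, file.path(dir, paste0(sid, ".bed")),
                     col_names = FALSE)
  }
  invisible(dir)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(dir) {
  files <- list.files(dir, pattern = "\\.bed$", full.names = TRUE)
  if (!length(files)) abort(sprintf("no fragment BED files in '%s'", dir))
  purrr::map_dfr(files, function(f) {
    fr <- readr::read_tsv(f, col_names = c("scaffold", "start", "end"),
                          show_col_types = FALSE)
    fr$sample_id <- sub("\\.bed$", "", basename(f))
    fr[, c("sample_id", "scaffold", "start", "end")]
  })
}
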