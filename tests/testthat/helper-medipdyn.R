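# shared fixture builders; everything is generated in code at test time

tiny_config <- function(...) {
  defaults <- list(
    n_scaffolds = 6, scaffold_length_range = c(46000, 70000),
    n_genes = 30, n_repeats = 10, n_tes = 20, seed = 42,
    dmr_plan = tibble::tibble(step = c("C", "M"), n = c(1L, 2L),
                              log2fc = 2, direction = "hyper")
  )
  dots <- list(...)
  args <- c(dots, defaults[setdiff(names(defaults), names(dots))])
  do.call(simulation_config, args)
}

# a medip_counts built directly from an integer matrix
make_counts <- function(m, stages, replicates, library_size = 1e6) {
  samples <- tibble::tibble(
    sample_id = colnames(m), stage = stages, replicate = replicates,
    library_size = rep_len(library_size, ncol(m))
  )
  tbl <- tibble::as_tibble(m)
  tbl <- tibble::add_column(tbl, element_id = rownames(m), .before = 1)
  medip_counts(tbl, samples)
}

# a medip_norm built directly from a cpm matrix (for test-crafted values)
make_norm <- function(cpm, stages, replicates = NULL, library_size = 1e6) {
  samples <- tibble::tibble(
    sample_id = colnames(cpm), stage = stages,
    replicate = replicates %||% stats::ave(seq_along(stages), stages,
                                           FUN = seq_along),
    library_size = rep_len(library_size, ncol(cpm))
  )
  to_tbl <- function(m) {
    tbl <- tibble::as_tibble(m)
    tibble::add_column(tbl, element_id = rownames(m), .before = 1)
  }
  structure(list(
    cpm = to_tbl(cpm), log_cpm = to_tbl(log2(cpm + 0.25)),
    counts = to_tbl(round(sweep(cpm, 2, samples$library_size / 1e6, "*"))),
    samples = samples
  ), class = c("medip_norm", "list"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# id-column tibble -> named matrix
as_mat <- function(tbl) {
  m <- as.matrix(tbl[, -1])
  rownames(m) <- tbl[[1]]
  m
}

# sample sheet for a subset of stages at fixed library size
flat_samples <- function(stages, n_rep = 3, library_size = 1e6) {
  tibble::tibble(
    sample_id = paste0(rep(stages, each = n_rep), "_r",
                       rep(seq_len(n_rep), length(stages))),
    stage = rep(stages, each = n_rep),
    replicate = rep(seq_len(n_rep), length(stages)),
    library_size = library_size
  )
}

# a one-scaffold annotation from an element spec tibble
manual_annotation <- function(elements, scaffold_length = 100000) {
  scaffolds <- tibble::tibble(
    scaffold = unique(elements$scaffold),
    length = scaffold_length
  )
  defaults <- tibble::tibble(
    gene_id = NA_character_, te_class = NA_character_, strand = "+"
  )
  for (col in names(defaults)) {
    if (!col %in% names(elements)) elements[[col]] <- defaults[[col]]
  }
  medip_annotation(scaffolds, elements)
}
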