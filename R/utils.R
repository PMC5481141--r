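#' @importFrom rlang .data abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join inner_join bind_rows n across all_of row_number rename count
#' @importFrom stats rnbinom rlnorm rgamma rnorm runif setNames sd var median
#'   chisq.test phyper wilcox.test oneway.test pairwise.t.test kmeans cor.test
#'   p.adjust pt qnorm quantile rpois cor complete.cases fisher.test aggregate
#' @importFrom utils head modifyList
NULL

# derive a reproducible substream seed (< 2^31) from a master seed and a label
substream_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  (as.integer(seed) * 101L + as.integer(h %% 100000L)) %% 2000000000L
}

with_substream <- function(seed, label, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, label))
  force(code)
}

stopifnot_scalar_number <- function(x, name, lower = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower) {
    abort(sprintf("`%s` must be a single number >= %s", name, format(lower)))
  }
  invisible(x)
}

# wide numeric matrix from a tibble with an id column
tbl_to_matrix <- function(tbl, id_col = 1L) {
  m <- as.matrix(tbl[, -id_col, drop = FALSE])
  rownames(m) <- tbl[[id_col]]
  storage.mode(m) <- "double"
  m
}

matrix_to_tbl <- function(m, id_name) {
  out <- as_tibble(m)
  out <- tibble::add_column(out, !!id_name := rownames(m), .before = 1L)
  out
}
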