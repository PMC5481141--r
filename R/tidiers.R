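#' @importFrom generics tidy glance
NULL

#' Tidy and glance methods for pipeline result objects
#'
#' Broom-style accessors: `tidy()` returns the per-unit result table,
#' `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name medipdyn-tidiers
NULL

#' @rdname medipdyn-tidiers
#' @export
tidy.medip_dmrs <- function(x, ...) {
  as_tibble(x)
}

#' @rdname medipdyn-tidiers
#' @export
glance.medip_dmrs <- function(x, ...) {
  design <- attr(x, "design")
  tibble(
    step = if (is.null(design)) NA_character_ else design$step,
    n_dmrs = nrow(x),
    n_hyper = sum(x$direction == "hyper"),
    n_hypo = sum(x$direction == "hypo"),
    median_length = if (nrow(x)) median(x$length) else NA_real_,
    dispersion = attr(x, "dispersion") %||% NA_real_
  )
}

#' @rdname medipdyn-tidiers
#' @export
tidy.medip_calls <- function(x, ...) x$stage_tally

#' @rdname medipdyn-tidiers
#' @export
glance.medip_calls <- function(x, ...) {
  g <- x$genes
  if (is.null(g)) {
    return(tibble(n_elements = nrow(x$elements)))
  }
  any_meth <- rowSums(as.matrix(g[, -1])) > 0
  tibble(n_elements = nrow(x$elements), n_genes = nrow(g),
         methylated_genes = sum(any_meth),
         unmethylated_genes = sum(!any_meth))
}

#' @rdname medipdyn-tidiers
#' @export
tidy.medip_dynamics <- function(x, ...) x$genes

#' @rdname medipdyn-tidiers
#' @export
glance.medip_dynamics <- function(x, ...) {
  tibble(n_tested = nrow(x$genes), n_dynamic = sum(x$genes$dynamic),
         dynamic_fraction = mean(x$genes$dynamic), alpha = x$alpha,
         n_skipped = x$n_skipped)
}

#' @rdname medipdyn-tidiers
#' @export
tidy.medip_kinetics_cor <- function(x, ...) as_tibble(x)

#' @rdname medipdyn-tidiers
#' @export
glance.medip_kinetics_cor <- function(x, ...) {
  tibble(
    n_tested = attr(x, "n_tested"),
    n_excluded = attr(x, "n_excluded"),
    coupled_fraction = attr(x, "coupled_fraction")
  )
}

#' @rdname medipdyn-tidiers
#' @export
tidy.medip_enrichment <- function(x, ...) as_tibble(x)

#' @rdname medipdyn-tidiers
#' @export
glance.medip_enrichment <- function(x, ...) {
  tibble(n_terms = nrow(x), n_sig_raw = sum(x$p_value < 0.05),
         min_p = if (nrow(x)) min(x$p_value) else NA_real_)
}
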