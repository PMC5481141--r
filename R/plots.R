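#' @importFrom ggplot2 autoplot ggplot aes geom_step geom_line geom_col
#'   geom_point geom_hline facet_wrap labs theme_minimal scale_colour_manual
NULL

#' Plot a physical methylation map
#'
#' One track per stage (or pooled stage group): mean normalised signal per
#' tiling window along the scaffold.
#'
#' @param object A [physical_map()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.medip_physical_map <- function(object, ...) {
  ggplot(object, aes(x = .data$start / 1000, y = .data$value)) +
    geom_step() +
    facet_wrap(~stage, ncol = 1) +
    labs(x = sprintf("position on %s (kb)", object$scaffold[1]),
         y = "methylation (cpm per window)") +
    theme_minimal()
}

#' MA-style plot of pairwise stage comparisons
#'
#' Mean log-cpm against log fold change per element, one panel per stage
#' pair, with significant elements highlighted.
#'
#' @param object A [pairwise_stage_tests()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.medip_pairwise <- function(object, ...) {
  ggplot(object, aes(x = .data$mean_log_cpm, y = .data$log_fc,
                     colour = .data$significant)) +
    geom_point(size = 0.4, alpha = 0.6) +
    geom_hline(yintercept = 0, linetype = 2) +
    facet_wrap(~ paste(.data$stage_a, "vs", .data$stage_b)) +
    scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    labs(x = "mean log2 cpm", y = "log2 fold change") +
    theme_minimal()
}

#' Plot DMR counts per developmental step
#' @param object A `medip_dmrs` tibble (steps may be concatenated).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.medip_dmrs <- function(object, ...) {
  d <- as_tibble(object) |> count(.data$step, .data$direction)
  ggplot(d, aes(x = .data$step, y = .data$n, fill = .data$direction)) +
    geom_col() +
    labs(x = "developmental step", y = "DMRs") +
    theme_minimal()
}

#' Plot kinetics cluster centroids
#' @param object A [cluster_kinetics()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.medip_clusters <- function(object, ...) {
  cen <- object$centroids |>
    tidyr::pivot_longer(-"cluster", names_to = "stage", values_to = "z") |>
    mutate(stage = factor(.data$stage, levels = medip_stages()))
  ggplot(cen, aes(x = .data$stage, y = .data$z, group = .data$cluster)) +
    geom_line() +
    geom_point(size = 1) +
    facet_wrap(~cluster) +
    labs(x = NULL, y = "methylation (z-score across stages)") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot decile trends of methylation against expression
#' @param deciles A [decile_trends()] result.
#' @return A ggplot with both decile axes.
#' @export
plot_decile_trends <- function(deciles) {
  d <- bind_rows(
    deciles$by_level |> mutate(axis = "expression level deciles") |>
      select("decile", "mean_methylation", "axis"),
    deciles$by_cv |> mutate(axis = "expression CV deciles") |>
      select("decile", "mean_methylation", "axis")
  )
  ggplot(d, aes(x = .data$decile, y = .data$mean_methylation)) +
    geom_col() +
    facet_wrap(~axis, scales = "free_y") +
    labs(x = "decile", y = "mean CDS methylation (cpm)") +
    theme_minimal()
}
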