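#' Simulate MeDIP feature counts from the ground truth
#'
#' Draws negative-binomial counts for every feature element and sample:
#' `counts ~ NB(mean = mu * library_size / 1e6, dispersion)`, where `mu` is
#' the truth's expected cpm for the element at the sample's stage and
#' per-sample library sizes come from [simulate_samples()]. A dispersion of
#' zero gives the Poisson limit. Reproducible for a fixed config seed.
#'
#' @param truth A [simulate_truth()] result.
#' @param annotation The matching [medip_annotation()].
#' @param config The same [simulation_config()].
#' @return A [medip_counts()] object.
#' @export
simulate_counts <- function(truth, annotation, config) {
  if (config$nb_dispersion < 0) abort("`nb_dispersion` must be >= 0")
  samples <- simulate_samples(config)
  mu <- tbl_to_matrix(truth$mu)
  with_substream(config$seed, "counts", {
    out <- matrix(0L, nrow = nrow(mu), ncol = nrow(samples),
                  dimnames = list(rownames(mu), samples$sample_id))
    for (j in seq_len(nrow(samples))) {
      m <- mu[, samples$stage[j]] * samples$library_size[j] / 1e6
      out[, j] <- if (config$nb_dispersion == 0) {
        rpois(length(m), m)
      } else {
        rnbinom(length(m), mu = m, size = 1 / config$nb_dispersion)
      }
    }
    medip_counts(matrix_to_tbl(out, "element_id"), samples)
  })
}

#' Simulate per-sample MeDIP fragments
#'
#' Generates fragment intervals (~250 bp, sonication-like) along each
#' scaffold from the truth's mosaic intensity: every 100 bp bin has an
#' expected fragment count equal to the mosaic base rate (methylated vs
#' unmethylated block), times any planted DMR fold active at the sample's
#' stage, times the sample's library-size factor; counts are
#' negative-binomial with the configured dispersion. These fragments feed
#' the fragment counter ([count_fragments()]) and the sliding-window DMR
#' caller.
#'
#' @param truth A [simulate_truth()] result.
#' @param annotation The matching [medip_annotation()].
#' @param config The same [simulation_config()].
#' @param samples Optional subset of the sample sheet (rows of
#'   [simulate_samples()]); fragments for a sample are identical whether or
#'   not other samples are generated.
#' @param scaffolds Optional character vector restricting generation to a
#'   scaffold subset (per-scaffold output is unaffected by the subset).
#' @param binwidth Elementary bin width in bp.
#' @return Tibble with `sample_id`, `scaffold`, `start`, `end` (0-based
#'   half-open fragment intervals).
#' @export
simulate_fragments <- function(truth, annotation, config, samples = NULL,
                               scaffolds = NULL, binwidth = 100) {
  samples <- samples %||% simulate_samples(config)
  sc <- annotation$scaffolds
  if (!is.null(scaffolds)) sc <- sc[sc$scaffold %in% scaffolds, ]
  out <- vector("list", nrow(samples))
  for (j in seq_len(nrow(samples))) {
    lib_factor <- samples$library_size[j] / config$mean_library_size
    stage_idx <- match(samples$stage[j], config$stages)
    per_sc <- vector("list", nrow(sc))
    for (i in seq_len(nrow(sc))) {
      per_sc[[i]] <- with_substream(
        config$seed,
        paste0("fragments_", samples$sample_id[j], "_", sc$scaffold[i]), {
          rate <- truth_bin_rates(truth, sc$scaffold[i], sc$length[i],
                                  stage_idx, config, binwidth) * lib_factor
          n <- if (config$nb_dispersion == 0) {
            rpois(length(rate), rate)
          } else {
            rnbinom(length(rate), mu = rate, size = 1 / config$nb_dispersion)
          }
          tot <- sum(n)
          if (tot == 0) NULL else {
            bin_start <- rep.int((seq_along(rate) - 1L) * binwidth, n)
            centers <- bin_start + runif(tot, 0, binwidth)
            lens <- pmin(400, pmax(100, round(rnorm(tot, 250, 30))))
            s0 <- pmax(0, round(centers - lens / 2))
            e0 <- pmin(sc$length[i], s0 + lens)
            tibble(
              sample_id = samples$sample_id[j], scaffold = sc$scaffold[i],
              start = as.integer(s0), end = as.integer(e0)
            )
          }
        })
    }
    out[[j]] <- bind_rows(per_sc)
  }
  bind_rows(out)
}

# expected fragments per bin at reference library size for one scaffold/stage
truth_bin_rates <- function(truth, scaffold, scaffold_length, stage_idx,
                            config, binwidth = 100) {
  n_bins <- ceiling(scaffold_length / binwidth)
  centers <- (seq_len(n_bins) - 0.5) * binwidth
  rate <- rep(config$bin_rate_unmethylated, n_bins)
  seg <- truth$segments[truth$segments$scaffold == scaffold &
                          truth$segments$methylated, ]
  for (i in seq_len(nrow(seg))) {
    rate[centers >= seg$start[i] & centers < seg$end[i]] <-
      config$bin_rate_methylated
  }
  dm <- truth$dmrs[truth$dmrs$scaffold == scaffold, ]
  if (nrow(dm)) {
    for (i in seq_len(nrow(dm))) {
      if (stage_idx >= step_onset_index(dm$step[i])) {
        fold <- 2^(dm$log2fc[i] * if (dm$direction[i] == "hyper") 1 else -1)
        hit <- centers >= dm$start[i] & centers < dm$end[i]
        rate[hit] <- rate[hit] * fold
      }
    }
  }
  rate
}
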