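#' Generate the synthetic methylome ground truth
#'
#' Builds the layers the count and expression simulators draw from, and the
#' registry the recovery tests read back:
#' * a mosaic segmentation of every scaffold into methylated and
#'   unmethylated blocks (the invertebrate-typical alternating pattern),
#'   with the configured genome-wide methylated fraction;
#' * per-element, per-stage expected methylation intensities (expected cpm):
#'   methylated elements draw a gamma-distributed baseline, unmethylated
#'   elements a near-zero one; a configurable fraction of methylated genes
#'   is given stage-varying kinetics built from five smooth profile
#'   archetypes;
#' * planted DMRs per the config's `dmr_plan`, each lying inside a
#'   methylated mosaic block on the longest scaffolds, whose fold-change
#'   applies to all stages from the step's later group onwards;
#' * de novo methylated genes (unmethylated at oocyte, methylated from a
#'   later onset stage), placed adjacent to methylated blocks, sized so the
#'   planted persistence matches `1 - denovo_gene_fraction`;
#' * the coupled-gene set whose expression will track CDS methylation.
#'
#' @param annotation A [medip_annotation()], typically from
#'   [simulate_annotation()].
#' @param config The same [simulation_config()] used for the annotation.
#' @return A `medip_truth` object: list with `mu` (tibble, `element_id` plus
#'   one column per stage), `segments`, `dmrs`, `genes` (per-gene status
#'   flags), and the config.
#' @export
simulate_truth <- function(annotation, config) {
  with_substream(config$seed, "truth", {
    segments <- mosaic_segments(annotation$scaffolds,
                                config$methylated_region_fraction)
    el <- annotation$elements
    stages <- config$stages
    n_stage <- length(stages)

    genes <- gene_table(annotation)
    gene_meth <- interval_is_methylated(segments, genes$scaffold, genes$center)

    # gene-level flags ------------------------------------------------------
    meth_ids <- genes$gene_id[gene_meth]
    unmeth_genes <- genes[!gene_meth, ]
    n_meth <- length(meth_ids)
    f_dn <- config$denovo_gene_fraction
    n_denovo <- if (f_dn > 0 && n_meth > 0) {
      max(0L, round(f_dn / (1 - f_dn) * n_meth))
    } else 0L
    denovo_ids <- character()
    if (n_denovo > 0 && nrow(unmeth_genes) > 0) {
      d <- distance_to_methylated_segment(segments, unmeth_genes$scaffold,
                                          unmeth_genes$center)
      ord <- order(d, unmeth_genes$gene_id)
      denovo_ids <- unmeth_genes$gene_id[ord][seq_len(min(n_denovo,
                                                          nrow(unmeth_genes)))]
    }
    onset <- setNames(sample(2:n_stage, length(denovo_ids), replace = TRUE),
                      denovo_ids)

    n_dyn <- round(config$dynamic_gene_fraction * n_meth)
    dynamic_ids <- if (n_dyn > 0) meth_ids[sample.int(n_meth, n_dyn)] else character()
    n_cp <- round(config$expression_coupling_fraction * length(dynamic_ids))
    coupled_ids <- if (n_cp > 0) {
      dynamic_ids[sample.int(length(dynamic_ids), n_cp)]
    } else character()

    # per-element baseline intensities --------------------------------------
    el_gene_meth <- el$gene_id %in% meth_ids
    own_meth <- interval_is_methylated(segments, el$scaffold,
                                       element_centers(el))
    # gene parts inherit the gene's status so gene-level calls are coherent;
    # promoters, repeats and TEs follow their own mosaic position
    is_meth <- ifelse(el$feature_class %in% c("CDS", "INT"),
                      el_gene_meth, own_meth)
    n_el <- nrow(el)
    mu_base <- numeric(n_el)
    mu_base[is_meth] <- rgamma(sum(is_meth), shape = 4,
                               rate = 4 / config$mean_cpm_methylated)
    mu_base[!is_meth] <- rgamma(sum(!is_meth), shape = 1,
                                rate = 1 / config$mean_cpm_unmethylated)

    mu <- matrix(mu_base, nrow = n_el, ncol = n_stage,
                 dimnames = list(el$element_id, stages))

    # dynamic kinetics on CDS/INT of dynamic genes --------------------------
    if (length(dynamic_ids)) {
      arch <- kinetics_archetypes(n_stage)
      gene_arch <- sample(nrow(arch), length(dynamic_ids), replace = TRUE)
      gene_amp <- runif(length(dynamic_ids), 0.8, 1.6)
      names(gene_arch) <- names(gene_amp) <- dynamic_ids
      dyn_rows <- which(el$gene_id %in% dynamic_ids &
                          el$feature_class %in% c("CDS", "INT"))
      for (i in dyn_rows) {
        g <- el$gene_id[i]
        mu[i, ] <- mu[i, ] * 2^(gene_amp[g] * arch[gene_arch[g], ])
      }
    }

    # de novo genes: silent at oocyte, methylated from their onset stage ----
    if (length(denovo_ids)) {
      dn_rows <- which(el$gene_id %in% denovo_ids &
                         el$feature_class %in% c("CDS", "INT"))
      for (i in dn_rows) {
        g <- el$gene_id[i]
        high <- rgamma(1, shape = 4, rate = 4 / config$mean_cpm_methylated)
        prof <- rep(mu_base[i], n_stage)
        prof[onset[g]:n_stage] <- high
        mu[i, ] <- prof
      }
    }

    # planted DMRs inside methylated blocks on the longest scaffolds --------
    dmrs <- place_planted_dmrs(annotation, segments, config)
    if (nrow(dmrs)) {
      for (k in seq_len(nrow(dmrs))) {
        hit <- el$scaffold == dmrs$scaffold[k] &
          el$start >= dmrs$start[k] & el$end <= dmrs$end[k]
        if (any(hit)) {
          idx <- step_onset_index(dmrs$step[k]):n_stage
          fold <- 2^(dmrs$log2fc[k] *
                       if (dmrs$direction[k] == "hyper") 1 else -1)
          mu[hit, idx] <- mu[hit, idx] * fold
        }
      }
    }

    gene_flags <- tibble(
      gene_id = genes$gene_id,
      methylated = gene_meth | genes$gene_id %in% denovo_ids,
      oocyte_methylated = gene_meth,
      dynamic = genes$gene_id %in% dynamic_ids,
      coupled = genes$gene_id %in% coupled_ids,
      denovo = genes$gene_id %in% denovo_ids,
      onset_stage = ifelse(genes$gene_id %in% denovo_ids,
                           stages[onset[genes$gene_id]], NA_character_)
    )

    structure(list(
      mu = matrix_to_tbl(mu, "element_id"),
      segments = segments,
      dmrs = dmrs,
      genes = gene_flags,
      config = config
    ), class = c("medip_truth", "list"))
  })
}

#' @export
print.medip_truth <- function(x, ...) {
  cat("<medip_truth>\n")
  cat(sprintf("  %d elements x %d stages; %d planted DMRs; %d/%d methylated genes (%d dynamic, %d coupled, %d de novo)\n",
              nrow(x$mu), ncol(x$mu) - 1L, nrow(x$dmrs),
              sum(x$genes$methylated), nrow(x$genes),
              sum(x$genes$dynamic), sum(x$genes$coupled),
              sum(x$genes$denovo)))
  invisible(x)
}

# alternating methylated/unmethylated blocks; expected genome-wide
# methylated coverage equals `fraction`
mosaic_segments <- function(scaffolds, fraction) {
  out <- vector("list", nrow(scaffolds))
  for (i in seq_len(nrow(scaffolds))) {
    len <- scaffolds$length[i]
    if (fraction <= 0 || fraction >= 1) {
      out[[i]] <- tibble(scaffold = scaffolds$scaffold[i], start = 0L,
                         end = as.integer(len),
                         methylated = fraction >= 1)
      next
    }
    meth_mean <- 12500
    unmeth_mean <- meth_mean * (1 - fraction) / fraction
    state <- runif(1) < fraction
    pos <- 0
    starts <- integer(); ends <- integer(); states <- logical()
    while (pos < len) {
      seg_len <- if (state) runif(1, 5000, 20000) else
        runif(1, 0.4 * unmeth_mean, 1.6 * unmeth_mean)
      seg_end <- min(len, round(pos + seg_len))
      starts <- c(starts, as.integer(pos))
      ends <- c(ends, as.integer(seg_end))
      states <- c(states, state)
      pos <- seg_end
      state <- !state
    }
    out[[i]] <- tibble(scaffold = scaffolds$scaffold[i], start = starts,
                       end = ends, methylated = states)
  }
  bind_rows(out)
}

# is each (scaffold, position) inside a methylated block?
# segments tile each scaffold contiguously, so findInterval on the sorted
# block starts identifies the block directly
interval_is_methylated <- function(segments, scaffold, position) {
  out <- logical(length(scaffold))
  for (sc in unique(scaffold)) {
    s <- segments[segments$scaffold == sc, ]
    s <- s[order(s$start), ]
    sel <- which(scaffold == sc)
    idx <- findInterval(position[sel], s$start)
    ok <- idx >= 1 & position[sel] < s$end[pmax(1L, idx)]
    out[sel] <- ok & s$methylated[pmax(1L, idx)]
  }
  out
}

# distance from a position to the nearest methylated block on its scaffold
distance_to_methylated_segment <- function(segments, scaffold, position) {
  out <- numeric(length(scaffold))
  for (sc in unique(scaffold)) {
    s <- segments[segments$scaffold == sc & segments$methylated, ]
    sel <- which(scaffold == sc)
    if (!nrow(s)) {
      out[sel] <- Inf
      next
    }
    out[sel] <- vapply(position[sel], function(p) {
      min(pmax(0, pmax(s$start - p, p - s$end)))
    }, numeric(1))
  }
  out
}

# five smooth stage-profile archetypes, each standardised across stages
kinetics_archetypes <- function(n_stage) {
  s <- seq(0, 1, length.out = n_stage)
  raw <- rbind(
    s,                         # monotone rise
    -s,                        # monotone fall
    exp(-((s - 0.15) / 0.2)^2),  # cleavage peak
    as.numeric(s > 0.85),      # metamorphosis switch
    exp(-((s - 0.5) / 0.25)^2)   # mid-larval plateau
  )
  t(apply(raw, 1, function(x) (x - mean(x)) / sd(x)))
}

place_planted_dmrs <- function(annotation, segments, config) {
  plan <- config$dmr_plan
  empty <- tibble(dmr_id = character(), scaffold = character(),
                  start = integer(), end = integer(), step = character(),
                  log2fc = numeric(), direction = character())
  if (!nrow(plan)) return(empty)
  sc <- annotation$scaffolds[order(-annotation$scaffolds$length,
                                   annotation$scaffolds$scaffold), ]
  min_len <- config$dmr_length_range[1]
  cand <- segments |>
    filter(.data$methylated, (.data$end - .data$start) >= min_len + 200) |>
    mutate(sc_rank = match(.data$scaffold, sc$scaffold)) |>
    arrange(.data$sc_rank, .data$start)
  total <- sum(plan$n)
  if (nrow(cand) < total) {
    abort(sprintf(
      "dmr_plan requests %d DMRs but only %d methylated blocks can host one",
      total, nrow(cand)
    ))
  }
  cand <- cand[seq_len(total), ]
  rows <- vector("list", total)
  k <- 0L
  for (p in seq_len(nrow(plan))) {
    for (j in seq_len(plan$n[p])) {
      k <- k + 1L
      seg <- cand[k, ]
      max_len <- min(config$dmr_length_range[2], seg$end - seg$start - 100)
      dlen <- round(runif(1, min_len, max(min_len, max_len)))
      s0 <- round(runif(1, seg$start, seg$end - dlen))
      rows[[k]] <- tibble(
        dmr_id = sprintf("planted_%s_%02d", plan$step[p], j),
        scaffold = seg$scaffold, start = as.integer(s0),
        end = as.integer(s0 + dlen), step = plan$step[p],
        log2fc = plan$log2fc[p], direction = plan$direction[p]
      )
    }
  }
  bind_rows(rows)
}
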