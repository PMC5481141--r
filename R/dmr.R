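#' Select scaffolds for region-level analyses
#'
#' DMR calling is restricted to the longest scaffolds: those strictly
#' longer than `min_length_bp`, capped at the `max_n` longest (ties broken
#' by scaffold name). The genome fraction covered by the selection is
#' attached as the `"genome_fraction"` attribute.
#'
#' @param annotation A [medip_annotation()].
#' @param min_length_bp Length floor in bp (strict; default 44000).
#' @param max_n Maximum number of scaffolds (default 2000).
#' @return Tibble of the selected scaffolds (`scaffold`, `length`), longest
#'   first.
#' @export
select_scaffolds <- function(annotation, min_length_bp = 44000, max_n = 2000) {
  sc <- annotation$scaffolds
  keep <- sc[sc$length > min_length_bp, ]
  keep <- keep[order(-keep$length, keep$scaffold), ]
  keep <- head(keep, max_n)
  if (!nrow(keep)) {
    warn("no scaffold passes the length floor")
  }
  attr(keep, "genome_fraction") <- sum(keep$length) / sum(sc$length)
  keep
}

#' Bin fragments into elementary windows
#'
#' Counts fragments per 100 bp (default) elementary bin per sample, by
#' fragment centre, on the given scaffolds. These bins are the unit from
#' which sliding windows and merged-region counts are built, so region
#' totals never double-count overlapping windows.
#'
#' @param fragments Tibble `sample_id`, `scaffold`, `start`, `end`.
#' @param scaffolds Tibble `scaffold`, `length` (e.g. from
#'   [select_scaffolds()]).
#' @param sample_ids Sample ids defining the count columns (defaults to the
#'   ids present in `fragments`).
#' @param binwidth Bin width in bp.
#' @return A `medip_bins` object.
#' @export
bin_fragments <- function(fragments, scaffolds, sample_ids = NULL,
                          binwidth = 100) {
  sample_ids <- sample_ids %||% sort(unique(fragments$sample_id))
  fragments <- fragments[fragments$scaffold %in% scaffolds$scaffold, ]
  center <- (fragments$start + fragments$end) %/% 2L
  counts <- vector("list", nrow(scaffolds))
  names(counts) <- scaffolds$scaffold
  for (i in seq_len(nrow(scaffolds))) {
    sc <- scaffolds$scaffold[i]
    n_bins <- as.integer(ceiling(scaffolds$length[i] / binwidth))
    sel <- fragments$scaffold == sc
    m <- matrix(0L, n_bins, length(sample_ids),
                dimnames = list(NULL, sample_ids))
    if (any(sel)) {
      bin <- pmin(n_bins, center[sel] %/% binwidth + 1L)
      sf <- factor(fragments$sample_id[sel], levels = sample_ids)
      tab <- table(factor(bin, levels = seq_len(n_bins)), sf)
      m[] <- as.integer(tab)
    }
    counts[[i]] <- m
  }
  structure(list(scaffolds = as_tibble(scaffolds), counts = counts,
                 sample_ids = sample_ids, binwidth = binwidth),
            class = c("medip_bins", "list"))
}

#' Sliding-window counts from elementary bins
#'
#' Rolling sums of the elementary bins: windows of `width` bp advanced by
#' `step` bp (both must be multiples of the bin width, with
#' `width >= step`).
#'
#' @param bins A [bin_fragments()] result.
#' @param width Window width in bp (default 1000).
#' @param step Window step in bp (default 100).
#' @return A `medip_windows` object: `windows` tibble (scaffold, start,
#'   end), `counts` matrix (windows x samples), plus the underlying bins.
#' @export
window_counts <- function(bins, width = 1000, step = 100) {
  bw <- bins$binwidth
  if (width < step) abort("window width must be >= step")
  if (width %% bw != 0 || step %% bw != 0) {
    abort("width and step must be multiples of the bin width")
  }
  k <- width %/% bw
  stride <- step %/% bw
  rows <- list(); mats <- list()
  for (sc in names(bins$counts)) {
    m <- bins$counts[[sc]]
    n_bins <- nrow(m)
    if (n_bins < k) next
    starts <- seq(1L, n_bins - k + 1L, by = stride)
    cs <- rbind(0, apply(m, 2, cumsum))
    wm <- cs[starts + k, , drop = FALSE] - cs[starts, , drop = FALSE]
    rows[[sc]] <- tibble(scaffold = sc, start = (starts - 1L) * bw,
                         end = (starts - 1L) * bw + width)
    mats[[sc]] <- wm
  }
  structure(list(windows = bind_rows(rows), counts = do.call(rbind, mats),
                 bins = bins, width = width, step = step),
            class = c("medip_windows", "list"))
}

#' Exact conditional negative-binomial test for two pooled count groups
#'
#' Tests equality of means between two groups of negative-binomial counts
#' with common dispersion, conditioning on the pooled total. With group
#' sizes `n_a`, `n_b` and dispersion `phi`, the group sums are NB with
#' sizes `r_a = n_a/phi`, `r_b = n_b/phi`; conditional on `s = s_a + s_b`
#' the distribution of `s_a` is beta-binomial-type and free of the mean,
#' so the test is exact. The two-sided p-value sums the probabilities of
#' all outcomes no more likely than the observed one (the same convention
#' as the exact binomial test, which is the `phi = 0` Poisson limit).
#'
#' @param s_a,s_b Pooled (library-size-adjusted, rounded) counts in each
#'   group.
#' @param n_a,n_b Number of samples in each group.
#' @param phi Common negative-binomial dispersion (>= 0; 0 = Poisson).
#' @return Two-sided p-value.
#' @export
#' @examples
#' nb_exact_test(40, 10, 3, 3, phi = 0.05)
nb_exact_test <- function(s_a, s_b, n_a, n_b, phi) {
  if (phi < 0) abort("dispersion must be >= 0")
  s <- s_a + s_b
  if (s == 0) return(1)
  a <- 0:s
  logf <- if (phi == 0) {
    stats::dbinom(a, s, n_a / (n_a + n_b), log = TRUE)
  } else {
    r_a <- n_a / phi
    r_b <- n_b / phi
    lgamma(a + r_a) - lgamma(a + 1) +
      lgamma(s - a + r_b) - lgamma(s - a + 1)
  }
  logf <- logf - max(logf)
  f <- exp(logf)
  sum(f[f <= f[s_a + 1] * (1 + 1e-7)]) / sum(f)
}

# method-of-moments common dispersion from per-window within-group
# mean/variance of adjusted counts: Var = m + phi m^2
common_dispersion_mom <- function(adj, groups) {
  num <- 0; den <- 0
  for (g in groups) {
    x <- adj[, g, drop = FALSE]
    n <- ncol(x)
    m <- rowMeans(x)
    v <- (rowSums(x^2) - n * m^2) / (n - 1)
    num <- num + sum(v - m)
    den <- den + sum(m^2)
  }
  max(1e-4, num / max(den, .Machine$double.eps))
}

#' Detect differentially methylated regions between two stage groups
#'
#' The caller of the pipeline's central statistic. Per sliding window
#' (1000 bp advanced by 100 bp by default), counts are adjusted to a
#' common library size, pooled within each group of the step design, and
#' tested with the exact conditional negative-binomial test
#' ([nb_exact_test()]) under a common method-of-moments dispersion.
#' Candidate windows (`p < window_p` and at least a 2-fold difference,
#' `|log2FC| >= min_lfc`) that overlap or abut, with the same direction,
#' are merged; every merged region is re-tested on its pooled elementary-
#' bin counts (dispersion rescaled to the region's bin span), and regions
#' of at least `min_length` bp with region `p < region_p` are emitted.
#'
#' @param windows A [window_counts()] result on the selected scaffolds.
#' @param samples Sample sheet with `sample_id`, `stage`, `library_size`.
#' @param design A [step_design()] (step C, I or M).
#' @param window_p Candidate window p-value cut-off (default 1e-4).
#' @param min_lfc Minimum |log2 fold change| (default 1, i.e. 2-fold).
#' @param region_p Region-level p-value cut-off (default 1e-7).
#' @param min_length Minimum region length in bp (default 1000).
#' @param prior_count Prior added per group mean when computing fold
#'   changes.
#' @return A `medip_dmrs` tibble: scaffold, start, end, step, length,
#'   log2fc, direction, p_value, center, n_windows.
#' @export
detect_dmrs <- function(windows, samples, design, window_p = 1e-4,
                        min_lfc = 1, region_p = 1e-7, min_length = 1000,
                        prior_count = 0.5) {
  grp <- design_groups(samples, design)
  wc <- windows$counts
  present <- intersect(c(grp$earlier, grp$later), colnames(wc))
  if (!setequal(present, c(grp$earlier, grp$later))) {
    abort("window counts lack samples required by the step design")
  }
  lib <- samples$library_size[match(colnames(wc), samples$sample_id)]
  adj_factor <- mean(lib) / lib
  adj <- sweep(wc, 2, adj_factor, "*")

  phi <- common_dispersion_mom(adj, list(grp$earlier, grp$later))
  n_a <- length(grp$earlier)
  n_b <- length(grp$later)
  s_a <- round(rowSums(adj[, grp$earlier, drop = FALSE]))
  s_b <- round(rowSums(adj[, grp$later, drop = FALSE]))
  lfc <- log2((s_b / n_b + prior_count) / (s_a / n_a + prior_count))

  cand <- which(abs(lfc) >= min_lfc)
  pvals <- rep(NA_real_, length(s_a))
  if (length(cand)) {
    key <- paste(s_a[cand], s_b[cand])
    uniq <- !duplicated(key)
    pu <- vapply(cand[uniq], function(i) {
      nb_exact_test(s_a[i], s_b[i], n_a, n_b, phi)
    }, numeric(1))
    pvals[cand] <- pu[match(key, key[uniq])]
  }
  is_cand <- !is.na(pvals) & pvals < window_p
  empty <- tibble(scaffold = character(), start = integer(), end = integer(),
                  step = character(), length = integer(), log2fc = numeric(),
                  direction = character(), p_value = numeric(),
                  center = numeric(), n_windows = integer())
  if (!any(is_cand)) {
    return(new_medip_dmrs(empty, design, phi))
  }

  cw <- windows$windows[is_cand, ]
  cw$direction <- ifelse(lfc[is_cand] > 0, "hyper", "hypo")
  regions <- merge_candidate_windows(cw)

  # region re-test on pooled elementary-bin counts
  bins <- windows$bins
  bw <- bins$binwidth
  phi_bin <- phi * (windows$width / bw)
  out <- vector("list", nrow(regions))
  for (i in seq_len(nrow(regions))) {
    r <- regions[i, ]
    m <- bins$counts[[r$scaffold]]
    b0 <- r$start %/% bw + 1L
    b1 <- min(nrow(m), as.integer(ceiling(r$end / bw)))
    reg_counts <- colSums(m[b0:b1, , drop = FALSE]) * adj_factor
    ra <- round(sum(reg_counts[grp$earlier]))
    rb <- round(sum(reg_counts[grp$later]))
    n_bins_reg <- b1 - b0 + 1L
    p_reg <- nb_exact_test(ra, rb, n_a, n_b, phi_bin / n_bins_reg)
    lfc_reg <- log2((rb / n_b + prior_count) / (ra / n_a + prior_count))
    out[[i]] <- tibble(
      scaffold = r$scaffold, start = r$start, end = r$end,
      step = design$step, length = as.integer(r$end - r$start),
      log2fc = lfc_reg,
      direction = ifelse(lfc_reg > 0, "hyper", "hypo"),
      p_value = p_reg, center = (r$start + r$end) / 2,
      n_windows = r$n_windows
    )
  }
  res <- bind_rows(out)
  res <- res[res$length >= min_length & res$p_value < region_p &
               abs(res$log2fc) >= min_lfc, ]
  if (!nrow(res)) res <- empty
  new_medip_dmrs(res, design, phi)
}

new_medip_dmrs <- function(tbl, design, phi) {
  structure(as_tibble(tbl),
            class = c("medip_dmrs", class(tibble())),
            design = design, dispersion = phi)
}

# merge overlapping or abutting candidate windows of the same direction
merge_candidate_windows <- function(cw) {
  cw <- cw[order(cw$scaffold, cw$direction, cw$start), ]
  out <- list()
  cur <- NULL
  flush <- function() if (!is.null(cur)) out[[length(out) + 1L]] <<- cur
  for (i in seq_len(nrow(cw))) {
    w <- cw[i, ]
    if (!is.null(cur) && cur$scaffold == w$scaffold &&
        cur$direction == w$direction && w$start <= cur$end) {
      cur$end <- max(cur$end, w$end)
      cur$n_windows <- cur$n_windows + 1L
    } else {
      flush()
      cur <- tibble(scaffold = w$scaffold, start = w$start, end = w$end,
                    direction = w$direction, n_windows = 1L)
    }
  }
  flush()
  bind_rows(out)
}

#' @export
print.medip_dmrs <- function(x, ...) {
  design <- attr(x, "design")
  cat(sprintf("<medip_dmrs> step %s: %d region(s)\n",
              if (is.null(design)) "?" else design$step, nrow(x)))
  NextMethod()
}

#' Annotate DMRs with fully-covered feature elements
#'
#' An element is annotated to a DMR only when the DMR completely covers it
#' (element start and end within the DMR interval); DMRs covering no
#' element are labelled not-annotated. Also tallies annotated elements per
#' feature class per step.
#'
#' @param dmrs A `medip_dmrs` tibble (one step or several concatenated;
#'   must have a `step` column).
#' @param annotation A [medip_annotation()].
#' @return List: `dmrs` (input plus `annotations` list-column of element
#'   ids and `n_annotated`), `tally` (step x feature_class counts,
#'   including `"not_annotated"` DMR counts).
#' @export
annotate_dmrs <- function(dmrs, annotation) {
  el <- annotation$elements
  ann <- vector("list", nrow(dmrs))
  if (nrow(dmrs)) {
    for (i in seq_len(nrow(dmrs))) {
      hit <- el$scaffold == dmrs$scaffold[i] &
        el$start >= dmrs$start[i] & el$end <= dmrs$end[i]
      ann[[i]] <- el$element_id[hit]
    }
  }
  out <- as_tibble(dmrs)
  out$annotations <- ann
  out$n_annotated <- lengths(ann)

  tally <- if (nrow(out)) {
    long <- out |>
      select("step", "annotations", "n_annotated") |>
      mutate(row = row_number())
    covered <- long |>
      filter(.data$n_annotated > 0) |>
      tidyr::unnest_longer("annotations", values_to = "element_id") |>
      mutate(feature_class =
               el$feature_class[match(.data$element_id, el$element_id)]) |>
      count(.data$step, .data$feature_class, name = "n")
    uncov <- long |>
      filter(.data$n_annotated == 0) |>
      count(.data$step, name = "n") |>
      mutate(feature_class = "not_annotated")
    bind_rows(covered, uncov) |>
      select("step", "feature_class", "n") |>
      arrange(.data$step, .data$feature_class)
  } else {
    tibble(step = character(), feature_class = character(), n = integer())
  }
  list(dmrs = out, tally = tally)
}

#' Distance from feature elements to the nearest DMR
#'
#' Distances are between central positions, per step, on the same scaffold
#' only; elements on scaffolds without a DMR for that step are reported
#' missing and excluded from class means.
#'
#' @param annotation A [medip_annotation()].
#' @param dmrs DMR tibble with `step`, `scaffold`, `center`.
#' @return List: `distances` (element-level tibble) and `class_means`
#'   (mean distance per feature class per step).
#' @export
distance_to_nearest_dmr <- function(annotation, dmrs) {
  el <- annotation$elements
  centers <- element_centers(el)
  steps <- unique(dmrs$step)
  rows <- vector("list", length(steps))
  for (k in seq_along(steps)) {
    d_step <- dmrs[dmrs$step == steps[k], ]
    dist <- rep(NA_real_, nrow(el))
    for (sc in unique(d_step$scaffold)) {
      cen <- d_step$center[d_step$scaffold == sc]
      sel <- el$scaffold == sc
      if (any(sel)) {
        dist[sel] <- vapply(centers[sel],
                            function(x) min(abs(x - cen)), numeric(1))
      }
    }
    rows[[k]] <- tibble(element_id = el$element_id,
                        feature_class = el$feature_class,
                        scaffold = el$scaffold, step = steps[k],
                        distance = dist)
  }
  distances <- bind_rows(rows)
  class_means <- distances |>
    filter(!is.na(.data$distance)) |>
    group_by(.data$step, .data$feature_class) |>
    summarise(mean_distance = mean(.data$distance), n = n(),
              .groups = "drop")
  list(distances = distances, class_means = class_means)
}

#' Transposable-element class contingency of DMRs
#'
#' Per step, counts DMR-annotated class I vs class II TEs, adds a genome
#' row (all TEs), computes class percentages, and tests independence with
#' Pearson's chi-square.
#'
#' @param annotated An [annotate_dmrs()] result (or its `dmrs` element).
#' @param annotation A [medip_annotation()].
#' @return List: `table` (tibble with class counts and percentages per row)
#'   and `chisq` (tidy tibble, or NULL if no TE-annotated DMRs).
#' @export
te_class_contingency <- function(annotated, annotation) {
  dmrs <- if (is.list(annotated) && !is.data.frame(annotated)) {
    annotated$dmrs
  } else {
    annotated
  }
  el <- annotation$elements
  te_class <- setNames(el$te_class, el$element_id)
  rows <- list()
  for (st in unique(dmrs$step)) {
    ids <- unlist(dmrs$annotations[dmrs$step == st])
    cls <- te_class[ids]
    cls <- cls[!is.na(cls)]
    rows[[st]] <- tibble(group = paste0("step_", st),
                         class_I = sum(cls == "I"),
                         class_II = sum(cls == "II"))
  }
  genome <- tibble(group = "genome",
                   class_I = sum(el$te_class == "I", na.rm = TRUE),
                   class_II = sum(el$te_class == "II", na.rm = TRUE))
  tab <- bind_rows(c(rows, list(genome))) |>
    mutate(pct_class_I = 100 * .data$class_I /
             pmax(1L, .data$class_I + .data$class_II))
  step_rows <- tab[tab$group != "genome", ]
  if (!nrow(step_rows) || all(step_rows$class_I + step_rows$class_II == 0)) {
    warn("no TE-annotated DMRs; chi-square test skipped")
    return(list(table = tab[tab$group != "genome" |
                              tab$class_I + tab$class_II > 0, ],
                chisq = NULL))
  }
  keep <- tab$class_I + tab$class_II > 0
  m <- as.matrix(tab[keep, c("class_I", "class_II")])
  rownames(m) <- tab$group[keep]
  list(table = tab, chisq = chi_square_independence(m))
}
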