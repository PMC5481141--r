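test_that("scaffold selection applies the strict length floor, cap and tie-break", {
  ann <- manual_annotation(tibble::tibble(
    element_id = "e1", scaffold = "sc_b", start = 0L, end = 100L,
    feature_class = "CDS", gene_id = "g1"
  ))
  ann$scaffolds <- tibble::tibble(
    scaffold = c("sc_b", "sc_a", "sc_c", "sc_d"),
    length = c(50000L, 45000L, 40000L, 45000L)
  )
  sel <- select_scaffolds(ann, min_length_bp = 44000)
  expect_equal(sel$scaffold, c("sc_b", "sc_a", "sc_d"))   # name breaks the tie
  expect_equal(attr(sel, "genome_fraction"),
               (50000 + 45000 + 45000) / 180000)
  expect_equal(select_scaffolds(ann, 44000, max_n = 1)$scaffold, "sc_b")
  expect_warning(sel0 <- select_scaffolds(ann, min_length_bp = 60000),
                 "floor")
  expect_equal(nrow(sel0), 0)
})

test_that("the exact NB test matches the binomial limit and a conditional NB oracle", {
  # Poisson limit: conditional distribution is binomial; same minimum-
  # likelihood two-sided convention as binom.test
  for (case in list(c(10, 30), c(0, 7), c(22, 19))) {
    p_nb <- nb_exact_test(case[1], case[2], 3, 3, phi = 0)
    p_bin <- binom.test(case[1], case[1] + case[2], 0.5)$p.value
    expect_equal(p_nb, p_bin, tolerance = 1e-9)
    p_bin2 <- binom.test(case[1], case[1] + case[2], 2 / 5)$p.value
    expect_equal(nb_exact_test(case[1], case[2], 2, 3, phi = 0), p_bin2,
                 tolerance = 1e-9)
  }
  # dispersed case: brute-force conditional probability from dnbinom
  # products; any common success probability gives the same answer
  oracle <- function(sa, sb, na, nb, phi, prob = 0.37) {
    s <- sa + sb
    f <- dnbinom(0:s, size = na / phi, prob = prob) *
      dnbinom(s - (0:s), size = nb / phi, prob = prob)
    f <- f / sum(f)
    sum(f[f <= f[sa + 1] * (1 + 1e-7)])
  }
  set.seed(2)
  for (i in 1:25) {
    sa <- rpois(1, 30); sb <- rpois(1, 70)
    phi <- runif(1, 0.01, 0.5)
    na <- sample(2:4, 1); nb <- sample(2:4, 1)
    expect_equal(nb_exact_test(sa, sb, na, nb, phi),
                 oracle(sa, sb, na, nb, phi), tolerance = 1e-7)
    expect_equal(oracle(sa, sb, na, nb, phi, prob = 0.8),
                 oracle(sa, sb, na, nb, phi, prob = 0.2), tolerance = 1e-9)
  }
  # symmetry and edge cases
  expect_equal(nb_exact_test(5, 40, 3, 3, 0.1), nb_exact_test(40, 5, 3, 3, 0.1))
  expect_equal(nb_exact_test(0, 0, 3, 3, 0.1), 1)
  expect_error(nb_exact_test(1, 1, 3, 3, -1), ">= 0")
})

test_that("the exact NB test agrees with edgeR's exact test at matched settings", {
  skip_if_not_installed("edgeR")
  # one pseudo-gene at a time, equal library sizes, fixed dispersion
  set.seed(8)
  for (i in 1:10) {
    counts <- matrix(rpois(6, 60), nrow = 1)
    phi <- 0.1
    d <- edgeR::DGEList(counts = rbind(counts, 50),
                        lib.size = rep(1e6, 6),
                        group = rep(c("a", "b"), each = 3))
    et <- edgeR::exactTest(d, dispersion = phi)
    p_pkg <- nb_exact_test(sum(counts[1:3]), sum(counts[4:6]), 3, 3, phi)
    # conventions differ slightly (doubled smaller tail vs minimum
    # likelihood); agreement within a factor tolerance is the check
    expect_equal(log(p_pkg), log(et$table$PValue[1]), tolerance = 0.15)
  }
})

test_that("windows slide correctly and merged regions re-test on pooled bins", {
  smp <- flat_samples(c("oocyte", "cells_2_8"), n_rep = 3,
                      library_size = 1e6)
  frs <- tibble::tibble(
    sample_id = rep(smp$sample_id, each = 2),
    scaffold = "sc1",
    start = rep(c(100L, 2100L), times = 6),
    end = rep(c(350L, 2350L), times = 6)
  )
  scaffolds <- tibble::tibble(scaffold = "sc1", length = 10000L)
  bins <- bin_fragments(frs, scaffolds, sample_ids = smp$sample_id)
  expect_equal(nrow(bins$counts[["sc1"]]), 100)
  # fragment centres 225 and 2225 fall in bins 3 and 23
  expect_equal(unname(bins$counts[["sc1"]][3, ]), rep(1L, 6))
  expect_equal(unname(bins$counts[["sc1"]][23, ]), rep(1L, 6))
  w <- window_counts(bins, width = 1000, step = 100)
  expect_equal(w$windows$start[1:3], c(0L, 100L, 200L))
  # window [0,1000) holds the first fragment only
  expect_equal(unname(w$counts[1, 1]), 1L)
  expect_error(window_counts(bins, width = 100, step = 1000), ">= step")
})

test_that("identical group means yield no DMRs and planted signal is recovered", {
  plan <- tibble::tibble(step = "C", n = 1L, log2fc = 2, direction = "hyper")
  cfg <- tiny_config(n_scaffolds = 2, scaffold_length_range = c(50000, 60000),
                     n_genes = 10, n_repeats = 4, n_tes = 6,
                     dmr_plan = plan, dmr_length_range = c(5000, 5000),
                     seed = 21)
  ann <- simulate_annotation(cfg)
  tr <- simulate_truth(ann, cfg)
  smp <- simulate_samples(cfg)
  sub <- smp[smp$stage %in% c("oocyte", "cells_2_8"), ]
  frs <- simulate_fragments(tr, ann, cfg, samples = sub)
  sel <- select_scaffolds(ann, 44000)
  w <- window_counts(bin_fragments(frs, sel, sample_ids = sub$sample_id))
  d <- detect_dmrs(w, sub, step_design("C"))
  expect_equal(nrow(d), 1)
  planted <- tr$dmrs
  ov <- min(d$end, planted$end) - max(d$start, planted$start)
  expect_gte(ov / (planted$end - planted$start), 0.8)
  expect_equal(d$direction, "hyper")
  # every emitted DMR satisfies all three thresholds
  expect_true(all(d$length >= 1000 & abs(d$log2fc) >= 1 & d$p_value < 1e-7))

  # the same genome with no planted change at the M step: no DMRs
  d_m <- detect_dmrs(
    window_counts(bin_fragments(
      simulate_fragments(tr, ann, cfg,
                         samples = smp[smp$stage %in% c("dlarva", "spat"), ]),
      sel, sample_ids = smp$sample_id[smp$stage %in% c("dlarva", "spat")]
    )),
    smp, list(step = "M", earlier = "dlarva", later = "spat")
  )
  expect_equal(nrow(d_m), 0)
})

test_that("a planted 1.5-fold region stays below the 2-fold floor", {
  plan <- tibble::tibble(step = "C", n = 1L, log2fc = 1, direction = "hyper")
  cfg <- tiny_config(n_scaffolds = 2, scaffold_length_range = c(50000, 60000),
                     n_genes = 10, n_repeats = 4, n_tes = 6,
                     dmr_plan = plan, dmr_length_range = c(5000, 5000),
                     seed = 33)
  ann <- simulate_annotation(cfg)
  tr <- simulate_truth(ann, cfg)
  tr$dmrs$log2fc <- log2(1.5)    # soften the planted effect below the floor
  smp <- simulate_samples(cfg)
  sub <- smp[smp$stage %in% c("oocyte", "cells_2_8"), ]
  frs <- simulate_fragments(tr, ann, cfg, samples = sub)
  sel <- select_scaffolds(ann, 44000)
  w <- window_counts(bin_fragments(frs, sel, sample_ids = sub$sample_id))
  d <- detect_dmrs(w, sub, step_design("C"))
  expect_equal(nrow(d), 0)
})

test_that("swapping the group labels flips fold changes and keeps p-values", {
  plan <- tibble::tibble(step = "C", n = 1L, log2fc = 2, direction = "hyper")
  cfg <- tiny_config(n_scaffolds = 2, scaffold_length_range = c(50000, 60000),
                     n_genes = 10, n_repeats = 4, n_tes = 6,
                     dmr_plan = plan, dmr_length_range = c(5000, 5000),
                     seed = 21)
  ann <- simulate_annotation(cfg)
  tr <- simulate_truth(ann, cfg)
  smp <- simulate_samples(cfg)
  sub <- smp[smp$stage %in% c("oocyte", "cells_2_8"), ]
  frs <- simulate_fragments(tr, ann, cfg, samples = sub)
  sel <- select_scaffolds(ann, 44000)
  w <- window_counts(bin_fragments(frs, sel, sample_ids = sub$sample_id))
  fwd <- detect_dmrs(w, sub, step_design("C"))
  rev <- detect_dmrs(w, sub, list(step = "C", earlier = "cells_2_8",
                                  later = "oocyte"))
  expect_equal(nrow(rev), nrow(fwd))
  expect_equal(rev$log2fc, -fwd$log2fc)
  expect_equal(rev$p_value, fwd$p_value)
  expect_equal(rev$direction, "hypo")
})

test_that("candidate-window merging is idempotent and direction-aware", {
  merge_fn <- medipdyn:::merge_candidate_windows
  cw <- tibble::tibble(
    scaffold = c("s1", "s1", "s1", "s1", "s2"),
    start = c(0L, 100L, 1100L, 5000L, 0L),
    end = c(1000L, 1100L, 2100L, 6000L, 1000L),
    direction = c("hyper", "hyper", "hyper", "hypo", "hyper")
  )
  m1 <- merge_fn(cw)
  # [0,1100) u [1100,2100) abut -> one region; hypo and s2 stay apart
  expect_equal(nrow(m1), 3)
  r1 <- m1[m1$scaffold == "s1" & m1$direction == "hyper", ]
  expect_equal(c(r1$start, r1$end), c(0L, 2100L))
  m2 <- merge_fn(m1[, c("scaffold", "start", "end", "direction")])
  expect_equal(m2[, c("scaffold", "start", "end", "direction")],
               m1[, c("scaffold", "start", "end", "direction")])
})

test_that("DMR annotation requires complete feature coverage", {
  ann <- manual_annotation(tibble::tibble(
    element_id = c("in_cds", "partial_cds", "te1"),
    scaffold = "sc1",
    start = c(1200L, 900L, 2400L),
    end = c(1800L, 1500L, 2600L),
    feature_class = c("CDS", "CDS", "TE"),
    gene_id = c("g1", "g2", NA),
    te_class = c(NA, NA, "I")
  ))
  dmrs <- tibble::tibble(
    scaffold = "sc1", start = c(1000L, 4000L), end = c(3000L, 5000L),
    step = "C", length = c(2000L, 1000L), log2fc = 2,
    direction = "hyper", p_value = 1e-9,
    center = c(2000, 4500), n_windows = 10L
  )
  res <- annotate_dmrs(dmrs, ann)
  expect_setequal(res$dmrs$annotations[[1]], c("in_cds", "te1"))
  expect_equal(res$dmrs$annotations[[2]], character(0))
  tally <- res$tally
  expect_equal(tally$n[tally$feature_class == "CDS"], 1)
  expect_equal(tally$n[tally$feature_class == "not_annotated"], 1)
})

test_that("distances to the nearest DMR use central positions per scaffold", {
  ann <- manual_annotation(tibble::tibble(
    element_id = c("e1", "e2"),
    scaffold = c("sc1", "sc2"),
    start = c(4500L, 100L), end = c(5500L, 300L),
    feature_class = c("CDS", "CDS"), gene_id = c("g1", "g2")
  ))
  ann$scaffolds <- tibble::tibble(scaffold = c("sc1", "sc2"),
                                  length = c(100000L, 100000L))
  dmrs <- tibble::tibble(step = "C", scaffold = "sc1",
                         center = c(2000, 9000))
  res <- distance_to_nearest_dmr(ann, dmrs)
  d <- res$distances
  expect_equal(d$distance[d$element_id == "e1"], 3000)   # min(3000, 4000)
  expect_true(is.na(d$distance[d$element_id == "e2"]))   # no DMR on sc2
  expect_equal(res$class_means$n, 1L)                    # NA excluded
})

test_that("TE-class contingency reproduces the published percentages", {
  # a synthetic annotation whose class counts mirror the printed table
  mk_te <- function(n1, n2, prefix) tibble::tibble(
    element_id = paste0(prefix, seq_len(n1 + n2)),
    scaffold = "sc1",
    start = seq(0L, by = 200L, length.out = n1 + n2),
    end = seq(100L, by = 200L, length.out = n1 + n2),
    feature_class = "TE", gene_id = NA_character_,
    te_class = rep(c("I", "II"), c(n1, n2)), strand = "+"
  )
  ann <- manual_annotation(mk_te(130, 90, "te"), scaffold_length = 200000)
  dmr_c <- tibble::tibble(
    scaffold = "sc1", start = 0L, end = 1000L, step = "C",
    annotations = list(c(paste0("te", 1:122), paste0("te", 131:211)))
  )
  dmr_m <- tibble::tibble(
    scaffold = "sc1", start = 0L, end = 1000L, step = "M",
    annotations = list(c(paste0("te", 1:121), paste0("te", 131:193)))
  )
  res <- te_class_contingency(list(dmrs = dplyr::bind_rows(dmr_c, dmr_m)), ann)
  tab <- res$table
  expect_equal(tab$class_I[tab$group == "step_C"], 122)
  expect_equal(tab$class_II[tab$group == "step_C"], 81)
  expect_equal(round(tab$pct_class_I[tab$group == "step_C"], 1), 60.1)
  # 121/(121+63) = 65.76%; the published table prints 65.7 vs 34.2 for
  # the same counts (rounding to 99.9% total)
  expect_equal(round(tab$pct_class_I[tab$group == "step_M"], 1), 65.8)
  expect_equal(round(tab$pct_class_I[tab$group == "genome"], 1), 59.1)
  expect_false(is.null(res$chisq))

  # equal counts give 50%
  dmr_eq <- tibble::tibble(
    scaffold = "sc1", start = 0L, end = 1000L, step = "C",
    annotations = list(c("te1", "te131"))
  )
  res_eq <- te_class_contingency(list(dmrs = dmr_eq), ann)
  expect_equal(res_eq$table$pct_class_I[res_eq$table$group == "step_C"], 50)

  # no TE-annotated DMRs: table kept, test skipped with a warning
  dmr_none <- tibble::tibble(
    scaffold = "sc1", start = 0L, end = 1000L, step = "C",
    annotations = list(character(0))
  )
  expect_warning(res0 <- te_class_contingency(list(dmrs = dmr_none), ann),
                 "skipped")
  expect_null(res0$chisq)
})
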