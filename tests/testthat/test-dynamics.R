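test_that("pairwise stage t-tests match the closed-form Student t", {
  # hand case: (1,2,3) vs (4,5,6) -> pooled t = -3.674, p ~ 0.0214
  tt <- medipdyn:::row_student_t(matrix(c(1, 2, 3), 1), matrix(c(4, 5, 6), 1))
  expect_equal(unname(tt$t), -3 / sqrt(2 / 3), tolerance = 1e-6)
  expect_equal(round(unname(tt$t), 3), -3.674)
  expect_equal(unname(tt$p), 0.0213, tolerance = 5e-3)
  # randomised agreement with t.test(var.equal = TRUE)
  set.seed(5)
  for (i in 1:20) {
    a <- rnorm(3); b <- rnorm(4, 1)
    got <- medipdyn:::row_student_t(matrix(a, 1), matrix(b, 1))
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(unname(got$t), unname(ref$statistic), tolerance = 1e-10)
    expect_equal(unname(got$p), ref$p.value, tolerance = 1e-10)
  }
})

test_that("pairwise tests flag separation and handle degenerate inputs", {
  cpm <- rbind(
    same = c(4, 4, 4, 4, 4, 4),
    shift = c(3.7, 4.1, 4.2, 15.3, 16.2, 15.8),
    degen = c(1, 1, 1, 7, 7, 7)
  )
  # jitter 'same' minimally so variance exists but means match
  colnames(cpm) <- paste0(rep(c("oocyte", "cells_2_8"), each = 3), "_r", 1:3)
  norm <- make_norm(cpm, stages = rep(c("oocyte", "cells_2_8"), each = 3))
  res <- pairwise_stage_tests(norm, pairs = cbind("oocyte", "cells_2_8"))
  expect_equal(res$t[res$element_id == "same"], 0)
  expect_equal(res$p_value[res$element_id == "same"], 1)
  expect_true(res$significant[res$element_id == "shift"])
  expect_true(res$degenerate[res$element_id == "degen"])
  expect_equal(res$p_value[res$element_id == "degen"], 0)
})

test_that("null pairwise p-values are approximately uniform", {
  set.seed(14)
  n <- 4000
  cpm <- matrix(2^rnorm(n * 6, 3, 1), nrow = n,
                dimnames = list(paste0("e", seq_len(n)),
                                paste0(rep(c("oocyte", "spat"), each = 3),
                                       "_r", 1:3)))
  norm <- make_norm(cpm, stages = rep(c("oocyte", "spat"), each = 3))
  res <- pairwise_stage_tests(norm, pairs = cbind("oocyte", "spat"))
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_equal(mean(res$p_value < 0.05), 0.05, tolerance = 0.35)
})

test_that("the ANOVA F statistic matches a brute-force sum-of-squares oracle", {
  # one-CDS genes so the gene-level value is the element value
  ann <- manual_annotation(tibble::tibble(
    element_id = paste0("g", 1:3, "_CDS1"),
    scaffold = "sc1",
    start = c(0L, 1000L, 2000L), end = c(500L, 1500L, 2500L),
    feature_class = "CDS", gene_id = paste0("g", 1:3)
  ))
  set.seed(31)
  stages <- rep(c("oocyte", "cells_2_8", "spat"), each = 2)
  cpm <- matrix(2^rnorm(18, 4, 1), nrow = 3,
                dimnames = list(paste0("g", 1:3, "_CDS1"),
                                paste0(stages, "_r", rep(1:2, 3))))
  norm <- make_norm(cpm, stages = stages)
  dyn <- anova_dynamic_selection(norm, ann, posthoc = FALSE)

  brute_f <- function(y, g) {
    g <- factor(g)
    grand <- mean(y)
    ss_between <- sum(tapply(y, g, function(v) length(v) * (mean(v) - grand)^2))
    ss_within <- sum(tapply(y, g, function(v) sum((v - mean(v))^2)))
    df_b <- nlevels(g) - 1
    df_w <- length(y) - nlevels(g)
    (ss_between / df_b) / (ss_within / df_w)
  }
  for (g in paste0("g", 1:3)) {
    y <- log2(cpm[paste0(g, "_CDS1"), ] + 0.25)
    expect_equal(dyn$genes$anova_f[dyn$genes$gene_id == g],
                 brute_f(y, stages), tolerance = 1e-8)
  }
})

test_that("a strongly shifted stage is selected and post-hoc contrasts localise it", {
  ann <- manual_annotation(tibble::tibble(
    element_id = "g1_CDS1", scaffold = "sc1", start = 0L, end = 500L,
    feature_class = "CDS", gene_id = "g1"
  ))
  stages <- rep(medip_stages(), each = 3)
  set.seed(7)
  vals <- 2^rnorm(24, 4, 0.2)
  vals[stages == "spat"] <- 2^rnorm(3, 9, 0.2)   # ~5 SD shift at spat
  cpm <- matrix(vals, nrow = 1,
                dimnames = list("g1_CDS1", paste0(stages, "_r", rep(1:3, 8))))
  norm <- make_norm(cpm, stages = stages)
  dyn <- anova_dynamic_selection(norm, ann, alpha = 0.01)
  expect_true(dyn$genes$dynamic)
  ph <- dyn$posthoc
  spat_rows <- ph[ph$stage_a == "spat" | ph$stage_b == "spat", ]
  other_rows <- ph[ph$stage_a != "spat" & ph$stage_b != "spat", ]
  expect_true(all(spat_rows$significant))
  expect_false(any(other_rows$significant))
})

test_that("K-means clustering recovers planted archetypes deterministically", {
  arch <- medipdyn:::kinetics_archetypes(8)[1:3, ]
  set.seed(12)
  prof <- arch[rep(1:3, each = 30), ] + matrix(rnorm(90 * 8, 0, 0.12), 90, 8)
  colnames(prof) <- medip_stages()
  tbl <- tibble::as_tibble(prof)
  tbl <- tibble::add_column(tbl, gene_id = paste0("g", 1:90), .before = 1)
  cl <- cluster_kinetics(tbl, k = 3, seed = 4)
  truth_lab <- rep(1:3, each = 30)
  tab <- table(cl$assignments$cluster, truth_lab)
  expect_true(all(apply(tab, 2, function(x) sum(x > 0)) == 1))  # pure
  expect_true(all(apply(tab, 1, function(x) sum(x > 0)) == 1))
  cl2 <- cluster_kinetics(tbl, k = 3, seed = 4)
  expect_identical(cl$assignments, cl2$assignments)

  # k = 1: single cluster, centroid is the profile mean (z-scored space)
  z <- t(scale(t(as.matrix(tbl[, -1]))))
  c1 <- cluster_kinetics(tbl, k = 1, seed = 1)
  expect_true(all(c1$assignments$cluster == 1))
  expect_equal(unname(as.matrix(c1$centroids[, -1])[1, ]),
               unname(colMeans(z)), tolerance = 1e-10)

  # restarts never worsen the objective
  c_few <- with(list(), {
    set.seed(99)
    cluster_kinetics(tbl, k = 3, seed = 2, restarts = 1)
  })
  c_many <- cluster_kinetics(tbl, k = 3, seed = 2, restarts = 25)
  expect_lte(c_many$tot_withinss, c_few$tot_withinss + 1e-9)

  expect_error(cluster_kinetics(tbl[1:2, ], k = 3), "k = 3")
})

test_that("physical maps tile the scaffold and conserve total signal", {
  smp <- flat_samples(c("oocyte", "spat"), n_rep = 2, library_size = 1e6)
  # uniform fragments: one per bin centre across [0, 40 kb)
  frs <- tidyr::expand_grid(
    sample_id = smp$sample_id,
    start = seq(0L, 39900L, by = 100L)
  ) |>
    dplyr::mutate(scaffold = "sc1", end = start + 100L)
  scaffolds <- tibble::tibble(scaffold = "sc1", length = 40000L)
  bins <- bin_fragments(frs, scaffolds, sample_ids = smp$sample_id)
  pm <- physical_map(bins, smp, "sc1", width = 10000)
  expect_equal(nrow(pm), 4 * 2)               # 4 windows x 2 stages
  expect_true(all(pm$value == pm$value[1]))   # flat track
  # totals are invariant to the window width
  pm2 <- physical_map(bins, smp, "sc1", width = 5000)
  tot <- function(x) sum(x$value[x$stage == "oocyte"])
  expect_equal(tot(pm), tot(pm2))
  # width beyond the scaffold gives a single window holding everything
  pm3 <- physical_map(bins, smp, "sc1", width = 100000)
  expect_equal(nrow(pm3), 2)
  expect_equal(tot(pm3), tot(pm))

  # localised signal lands in exactly one 10 kb window
  frs_loc <- tibble::tibble(
    sample_id = rep(smp$sample_id, each = 5),
    scaffold = "sc1",
    start = rep(seq(21000L, 29000L, by = 2000L), 4)
  ) |>
    dplyr::mutate(end = start + 250L)
  bins_loc <- bin_fragments(frs_loc, scaffolds, sample_ids = smp$sample_id)
  pm_loc <- physical_map(bins_loc, smp, "sc1", width = 10000)
  nz <- pm_loc[pm_loc$stage == "oocyte" & pm_loc$value > 0, ]
  expect_equal(nrow(nz), 1)
  expect_equal(nz$start, 20000)
})

test_that("persistence counts later-stage methylated genes already methylated earlier", {
  genes <- tibble::tibble(
    gene_id = c("A", "B", "C"),
    oocyte = c(TRUE, TRUE, FALSE),
    spat = c(TRUE, TRUE, TRUE)
  )
  calls <- structure(list(genes = genes), class = c("medip_calls", "list"))
  res <- persistence(calls)
  expect_equal(res$fraction, 2 / 3)
  expect_equal(res$de_novo_genes, "C")
  genes2 <- genes; genes2$spat <- genes2$oocyte
  res2 <- persistence(structure(list(genes = genes2),
                                class = c("medip_calls", "list")))
  expect_equal(res2$fraction, 1)
  genes3 <- genes; genes3$spat <- FALSE
  expect_warning(
    res3 <- persistence(structure(list(genes = genes3),
                                  class = c("medip_calls", "list"))),
    "undefined"
  )
  expect_true(is.na(res3$fraction))
})
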