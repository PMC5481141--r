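test_that("generated gene models have the requested structure", {
  cfg <- tiny_config(n_genes = 10, exons_per_gene = c(3, 3))
  ann <- simulate_annotation(cfg)
  el <- ann$elements
  expect_equal(length(unique(el$gene_id[!is.na(el$gene_id)])), 10)
  per_gene <- table(el$gene_id, el$feature_class)
  expect_true(all(per_gene[, "CDS"] == 3))
  expect_true(all(per_gene[, "INT"] == 2))
  expect_true(all(per_gene[, "PRO"] == 1))
  # elements never overlap and stay inside their scaffold
  by_sc <- split(el, el$scaffold)
  for (s in by_sc) {
    s <- s[order(s$start), ]
    expect_true(all(head(s$end, -1) <= s$start[-1]))
  }
  # promoter lengths straddle the 100 bp filter boundary across seeds
  pro_len <- with(el[el$feature_class == "PRO", ], end - start)
  expect_true(any(pro_len <= 100) && any(pro_len > 100))
})

test_that("TE class labels follow the configured fraction", {
  ann1 <- simulate_annotation(tiny_config(te_class1_fraction = 1.0))
  expect_true(all(ann1$elements$te_class[
    ann1$elements$feature_class == "TE"] == "I"))
  ann0 <- simulate_annotation(tiny_config(te_class1_fraction = 0))
  expect_true(all(ann0$elements$te_class[
    ann0$elements$feature_class == "TE"] == "II"))
})

test_that("annotation generation is deterministic and file-identical under a seed", {
  cfg <- tiny_config(seed = 7)
  a1 <- simulate_annotation(cfg)
  a2 <- simulate_annotation(cfg)
  expect_identical(a1$elements, a2$elements)
  f1 <- tempfile(fileext = ".gff3"); f2 <- tempfile(fileext = ".gff3")
  write_annotation(a1, f1, "gff3")
  write_annotation(a2, f2, "gff3")
  expect_identical(readLines(f1), readLines(f2))
})

test_that("an over-packed genome raises a sizing error", {
  cfg <- tiny_config(n_scaffolds = 2, scaffold_length_range = c(46000, 48000),
                     n_genes = 200)
  expect_error(simulate_annotation(cfg), "too short")
})

test_that("truth intensities are constant across stages in the no-signal case", {
  cfg <- tiny_config(dmr_plan = dmr_plan_none(), dynamic_gene_fraction = 0,
                     denovo_gene_fraction = 0)
  tr <- simulate_truth(simulate_annotation(cfg), cfg)
  mu <- as.matrix(tr$mu[, -1])
  expect_true(all(mu >= 0))
  expect_equal(apply(mu, 1, max), apply(mu, 1, min))
  expect_equal(nrow(tr$dmrs), 0)
})

test_that("a planted cleavage DMR multiplies covered intensities from the 2-8 cell stage on", {
  cfg <- tiny_config(
    dmr_plan = tibble::tibble(step = "C", n = 1L, log2fc = 2,
                              direction = "hyper"),
    dynamic_gene_fraction = 0, denovo_gene_fraction = 0,
    dmr_length_range = c(5000, 5000)
  )
  tr <- simulate_truth(simulate_annotation(cfg), cfg)
  expect_equal(nrow(tr$dmrs), 1)
  d <- tr$dmrs
  # planted regions lie inside a methylated mosaic block
  seg <- tr$segments[tr$segments$scaffold == d$scaffold &
                       tr$segments$methylated, ]
  expect_true(any(seg$start <= d$start & d$end <= seg$end))
  ann <- simulate_annotation(cfg)
  covered <- ann$elements$element_id[
    ann$elements$scaffold == d$scaffold &
      ann$elements$start >= d$start & ann$elements$end <= d$end]
  skip_if(length(covered) == 0, "no element fully inside the planted region")
  mu <- tr$mu[tr$mu$element_id %in% covered, ]
  expect_equal(mu$cells_2_8, 4 * mu$oocyte)
  expect_equal(mu$spat, 4 * mu$oocyte)
})

test_that("the truth registry encodes the planted persistence", {
  cfg <- tiny_config(n_genes = 60, n_scaffolds = 10,
                     scaffold_length_range = c(50000, 90000),
                     denovo_gene_fraction = 0.05)
  tr <- simulate_truth(simulate_annotation(cfg), cfg)
  g <- tr$genes
  meth_spat <- g$methylated            # methylated at some stage through spat
  frac <- sum(meth_spat & g$oocyte_methylated) / sum(meth_spat)
  expect_gte(frac, 1 - 0.05 - 0.02)
  # de novo genes switch on strictly after the oocyte stage
  expect_true(all(!g$oocyte_methylated[g$denovo]))
  expect_true(all(!is.na(g$onset_stage[g$denovo])))
  expect_false(any(g$onset_stage[g$denovo] == "oocyte"))
})

test_that("over-subscribed DMR plans raise a capacity error", {
  cfg <- tiny_config(
    n_scaffolds = 2, n_genes = 5, n_repeats = 2, n_tes = 2,
    dmr_plan = tibble::tibble(step = "M", n = 500L, log2fc = 2,
                              direction = "hyper")
  )
  expect_error(simulate_truth(simulate_annotation(cfg), cfg), "capacity|host")
})

test_that("counts are zero when intensities are zero and match NB moments otherwise", {
  cfg0 <- tiny_config(methylated_region_fraction = 0,
                      mean_cpm_unmethylated = 0,
                      dynamic_gene_fraction = 0, denovo_gene_fraction = 0,
                      dmr_plan = dmr_plan_none())
  ann <- simulate_annotation(cfg0)
  tr0 <- simulate_truth(ann, cfg0)
  cm0 <- simulate_counts(tr0, ann, cfg0)
  expect_true(all(as.matrix(cm0$counts[, -1]) == 0))

  # Poisson limit and mean recovery, Monte-Carlo oracle over >= 1e4 draws
  mk_truth <- function(mu_value) {
    mu <- matrix(mu_value, nrow = nrow(tr0$mu), ncol = 8,
                 dimnames = list(tr0$mu$element_id, medip_stages()))
    tr <- tr0
    tbl <- tibble::as_tibble(mu)
    tr$mu <- tibble::add_column(tbl, element_id = rownames(mu), .before = 1)
    tr
  }
  cfg_pois <- tiny_config(nb_dispersion = 0, mean_library_size = 1e6)
  cm <- simulate_counts(mk_truth(50), ann, cfg_pois)
  m <- as.matrix(cm$counts[, -1])
  lib <- cm$samples$library_size
  for (j in seq_len(3)) {                       # 3 columns x >1200 elements
    expect_lt(abs(var(m[, j]) / mean(m[, j]) - 1), 4 * sqrt(2 / nrow(m)))
    mu_j <- 50 * lib[j] / 1e6
    expect_lt(abs(mean(m[, j]) - mu_j), 4 * sqrt(mu_j / nrow(m)))
  }
  # dispersed counts: var/mean == 1 + phi*mean within MC error
  cfg_nb <- tiny_config(nb_dispersion = 0.1, mean_library_size = 1e6)
  cm2 <- simulate_counts(mk_truth(20), ann, cfg_nb)
  m2 <- as.matrix(cm2$counts[, -1])
  mu2 <- 20 * cm2$samples$library_size[1] / 1e6
  expect_equal(var(m2[, 1]) / mean(m2[, 1]), 1 + 0.1 * mu2, tolerance = 0.25)
})

test_that("per-sample feature counts never exceed the library size", {
  cfg <- tiny_config()
  ann <- simulate_annotation(cfg)
  cm <- simulate_counts(simulate_truth(ann, cfg), ann, cfg)
  expect_true(all(colSums(as.matrix(cm$counts[, -1])) <=
                    cm$samples$library_size))
})

test_that("fragment simulation is reproducible and subset-stable", {
  cfg <- tiny_config(n_scaffolds = 3, n_genes = 10, n_repeats = 4, n_tes = 6)
  ann <- simulate_annotation(cfg)
  tr <- simulate_truth(ann, cfg)
  smp <- simulate_samples(cfg)
  sub <- smp[smp$stage %in% c("oocyte", "cells_2_8"), ]
  f1 <- simulate_fragments(tr, ann, cfg, samples = sub)
  f2 <- simulate_fragments(tr, ann, cfg, samples = sub)
  expect_identical(f1, f2)
  # restricting to one scaffold reproduces that scaffold's fragments
  sc1 <- ann$scaffolds$scaffold[1]
  f3 <- simulate_fragments(tr, ann, cfg, samples = sub, scaffolds = sc1)
  expect_identical(f3, f1[f1$scaffold == sc1, ])
})

test_that("expression simulation couples only the flagged genes and silences unmethylated ones", {
  cfg <- tiny_config(n_genes = 80, n_scaffolds = 10,
                     scaffold_length_range = c(60000, 90000),
                     expression_coupling_fraction = 0)
  ann <- simulate_annotation(cfg)
  tr <- simulate_truth(ann, cfg)
  expect_equal(sum(tr$genes$coupled), 0)

  cfg2 <- tiny_config(n_genes = 80, n_scaffolds = 10,
                      scaffold_length_range = c(60000, 90000),
                      expression_coupling_fraction = 1,
                      dynamic_gene_fraction = 0.5)
  tr2 <- simulate_truth(simulate_annotation(cfg2), cfg2)
  expr <- simulate_expression(tr2, cfg2)
  mu <- as.matrix(tr2$mu[, -1])
  rownames(mu) <- tr2$mu$element_id
  cds_gene <- sub("_CDS.*$", "", rownames(mu))
  is_cds <- grepl("_CDS", rownames(mu), fixed = TRUE)
  kin <- rowsum(mu[is_cds, ], cds_gene[is_cds])
  em <- as.matrix(expr[, -1]); rownames(em) <- expr$gene_id
  coupled <- tr2$genes$gene_id[tr2$genes$coupled]
  rs <- vapply(coupled, function(g) cor(kin[g, ], em[g, ]), numeric(1))
  expect_true(mean(rs > 0) > 0.9)   # positive correlation by construction
  # unmethylated genes are mostly silent relative to methylated ones
  meth <- tr2$genes$methylated
  expect_gt(median(rowMeans(em)[tr2$genes$gene_id[meth]]),
            10 * median(rowMeans(em)[tr2$genes$gene_id[!meth]]))
})

test_that("term annotation tables are deterministic and plant enrichment", {
  cfg <- tiny_config()
  ann <- simulate_annotation(cfg)
  t1 <- simulate_term_annotations(ann, n_terms = 20, seed = 3)
  t2 <- simulate_term_annotations(ann, n_terms = 20, seed = 3)
  expect_identical(t1, t2)
  genes <- sort(unique(ann$elements$gene_id))
  genes <- genes[!is.na(genes)]
  planted <- list(list(term_id = "term_hit", genes = genes[1:10], prob = 1))
  t3 <- simulate_term_annotations(ann, n_terms = 20,
                                  planted_enrichment = planted, seed = 3)
  expect_setequal(t3$gene_id[t3$term_id == "term_hit"], genes[1:10])
})
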