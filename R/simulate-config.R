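#' Simulation configuration for a synthetic MeDIP-seq experiment
#'
#' Bundles every parameter of the synthetic-data generator: genome geometry,
#' the eight-stage replicated design, the mosaic methylome, the planted-DMR
#' plan, negative-binomial count noise and the methylation-expression
#' coupling structure. Defaults emulate the oyster developmental design:
#' eight stages (oocyte to spat) with three biological replicates, a
#' class I/class II transposable-element split of 75.1/24.9%, differential
#' methylation concentrated at the cleavage (C) and metamorphosis (M) steps,
#' 26% of methylated genes with dynamic stage kinetics of which 10% have
#' methylation-coupled expression, and 1.3% de novo methylated genes (so
#' 98.7% of spat-methylated genes are already methylated in oocytes).
#'
#' @param n_scaffolds Number of genomic scaffolds.
#' @param scaffold_length_range Length range in bp; scaffolds are drawn
#'   uniformly in this range (the default straddles the 44 kb scaffold
#'   filter used for DMR calling).
#' @param n_genes Number of gene models (promoter + alternating CDS/intron).
#' @param exons_per_gene Integer range of exons per gene.
#' @param promoter_length_range Promoter length range in bp; must straddle
#'   100 bp so the promoter-length filter is exercised.
#' @param n_repeats,n_tes Numbers of repeat and transposable-element
#'   elements.
#' @param te_class1_fraction Proportion of TEs that are class I
#'   (retrotransposons); default 0.751.
#' @param stages Ordered stage labels; must be the 8-stage vocabulary.
#' @param replicates_per_stage Biological replicates per stage (2 or 3).
#' @param methylated_region_fraction Fraction of the genome lying in
#'   methylated mosaic segments.
#' @param dmr_plan Tibble with columns `step` (`"C"`, `"I"` or `"M"`), `n`,
#'   `log2fc` (>= 1) and `direction` (`"hyper"` or `"hypo"`): the planted
#'   differentially methylated regions. Use `dmr_plan_none()` for a null
#'   methylome.
#' @param dmr_length_range Planted DMR length range in bp.
#' @param nb_dispersion Negative-binomial dispersion of fragment counts.
#' @param mean_library_size Mean sequencing library size (fragments);
#'   per-sample sizes are log-normal around it with 10% CV.
#' @param mean_cpm_methylated Mean expected cpm of a methylated feature
#'   element; unmethylated elements average `mean_cpm_unmethylated`.
#' @param mean_cpm_unmethylated Mean expected cpm of an unmethylated element.
#' @param bin_rate_methylated Expected fragments per 100 bp bin per sample in
#'   methylated mosaic segments (sets the window depth seen by the DMR
#'   caller; 2.0 gives ~20 fragments per 1 kb window).
#' @param bin_rate_unmethylated Same, in unmethylated segments.
#' @param dynamic_gene_fraction Fraction of methylated genes given
#'   stage-varying (dynamic) methylation kinetics; default 0.26.
#' @param expression_coupling_fraction Fraction of dynamic methylated genes
#'   whose expression kinetics track their CDS methylation; default 0.10.
#' @param denovo_gene_fraction Target fraction of spat-methylated genes that
#'   are de novo methylated (unmethylated in oocytes); default 0.013.
#' @param seed Integer master seed; independent substreams are derived per
#'   generator component.
#'
#' @return A `medip_sim_config` list with the validated parameters.
#' @export
#' @examples
#' cfg <- simulation_config(n_genes = 50, seed = 1)
#' cfg$te_class1_fraction
simulation_config <- function(n_scaffolds = 30,
                              scaffold_length_range = c(30000, 220000),
                              n_genes = 400,
                              exons_per_gene = c(3, 8),
                              promoter_length_range = c(60, 400),
                              n_repeats = 150,
                              n_tes = 300,
                              te_class1_fraction = 0.751,
                              stages = medip_stages(),
                              replicates_per_stage = 3,
                              methylated_region_fraction = 0.5,
                              dmr_plan = dmr_plan_default(),
                              dmr_length_range = c(2000, 6000),
                              nb_dispersion = 0.05,
                              mean_library_size = 3.6e6,
                              mean_cpm_methylated = 30,
                              mean_cpm_unmethylated = 0.1,
                              bin_rate_methylated = 2,
                              bin_rate_unmethylated = 0.05,
                              dynamic_gene_fraction = 0.26,
                              expression_coupling_fraction = 0.10,
                              denovo_gene_fraction = 0.013,
                              seed = 1L) {
  for (p in c("te_class1_fraction", "methylated_region_fraction",
              "dynamic_gene_fraction", "expression_coupling_fraction",
              "denovo_gene_fraction")) {
    v <- get(p)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      abort(sprintf("`%s` must be a proportion in [0, 1]", p))
    }
  }
  if (!identical(as.character(stages), medip_stages())) {
    abort("`stages` must be the 8 ordered stage labels of medip_stages()")
  }
  if (!replicates_per_stage %in% 2:3) {
    abort("`replicates_per_stage` must be 2 or 3")
  }
  if (nb_dispersion < 0) abort("`nb_dispersion` must be >= 0")
  if (promoter_length_range[1] >= 100 || promoter_length_range[2] <= 100) {
    abort("`promoter_length_range` must straddle 100 bp")
  }
  stopifnot_scalar_number(n_scaffolds, "n_scaffolds", 1)
  stopifnot_scalar_number(n_genes, "n_genes", 1)
  stopifnot_scalar_number(mean_library_size, "mean_library_size", 1)
  dmr_plan <- validate_dmr_plan(dmr_plan)

  cfg <- list(
    n_scaffolds = as.integer(n_scaffolds),
    scaffold_length_range = scaffold_length_range,
    n_genes = as.integer(n_genes),
    exons_per_gene = as.integer(exons_per_gene),
    promoter_length_range = promoter_length_range,
    n_repeats = as.integer(n_repeats),
    n_tes = as.integer(n_tes),
    te_class1_fraction = te_class1_fraction,
    stages = as.character(stages),
    replicates_per_stage = as.integer(replicates_per_stage),
    methylated_region_fraction = methylated_region_fraction,
    dmr_plan = dmr_plan,
    dmr_length_range = dmr_length_range,
    nb_dispersion = nb_dispersion,
    mean_library_size = mean_library_size,
    mean_cpm_methylated = mean_cpm_methylated,
    mean_cpm_unmethylated = mean_cpm_unmethylated,
    bin_rate_methylated = bin_rate_methylated,
    bin_rate_unmethylated = bin_rate_unmethylated,
    dynamic_gene_fraction = dynamic_gene_fraction,
    expression_coupling_fraction = expression_coupling_fraction,
    denovo_gene_fraction = denovo_gene_fraction,
    seed = as.integer(seed)
  )
  structure(cfg, class = c("medip_sim_config", "list"))
}

#' Default and empty planted-DMR plans
#'
#' The default plan concentrates planted DMRs at the cleavage and
#' metamorphosis steps (the transitions at which the oyster methylome is
#' most regulated), with none at the intermediate step.
#'
#' @return A tibble with columns `step`, `n`, `log2fc`, `direction`.
#' @export
dmr_plan_default <- function() {
  tibble(
    step = c("C", "M"),
    n = c(6L, 12L),
    log2fc = c(2, 2),
    direction = c("hyper", "hyper")
  )
}

#' @rdname dmr_plan_default
#' @export
dmr_plan_none <- function() {
  tibble(step = character(), n = integer(), log2fc = numeric(),
         direction = character())
}

validate_dmr_plan <- function(plan) {
  plan <- as_tibble(plan)
  needed <- c("step", "n", "log2fc", "direction")
  if (!all(needed %in% names(plan))) {
    abort("`dmr_plan` needs columns step, n, log2fc, direction")
  }
  if (nrow(plan) > 0) {
    if (!all(plan$step %in% c("C", "I", "M"))) {
      abort("`dmr_plan$step` must be C, I or M")
    }
    if (any(plan$log2fc < 1)) abort("planted fold-changes must be >= 1 (log2)")
    if (!all(plan$direction %in% c("hyper", "hypo"))) {
      abort("`dmr_plan$direction` must be 'hyper' or 'hypo'")
    }
  }
  plan
}

#' @export
print.medip_sim_config <- function(x, ...) {
  cat("<medip_sim_config>\n")
  cat(sprintf("  genome: %d scaffolds (%s-%s bp), %d genes, %d REP, %d TE\n",
              x$n_scaffolds, format(x$scaffold_length_range[1], big.mark = ","),
              format(x$scaffold_length_range[2], big.mark = ","),
              x$n_genes, x$n_repeats, x$n_tes))
  cat(sprintf("  design: 8 stages x %d replicates, library ~%.2g fragments\n",
              x$replicates_per_stage, x$mean_library_size))
  cat(sprintf("  planted DMRs: %s\n",
              if (nrow(x$dmr_plan)) {
                paste(sprintf("%s:%d", x$dmr_plan$step, x$dmr_plan$n),
                      collapse = " ")
              } else "none"))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# first stage index (1-based, oocyte = 1) at which a step's effect applies
step_onset_index <- function(step) {
  switch(step, C = 2L, I = 3L, M = 8L,
         abort(sprintf("unknown step '%s'", step)))
}

#' Sample sheet for a simulated experiment
#'
#' Draws per-sample library sizes (log-normal around the configured mean,
#' 10% coefficient of variation) and lays out the stage x replicate design.
#' Deterministic for a fixed config seed, and shared by the count and
#' fragment simulators so both describe the same samples.
#'
#' @param config A [simulation_config()].
#' @return Tibble with columns `sample_id`, `stage`, `replicate`,
#'   `library_size`.
#' @export
simulate_samples <- function(config) {
  with_substream(config$seed, "samples", {
    stages <- rep(config$stages, each = config$replicates_per_stage)
    reps <- rep(seq_len(config$replicates_per_stage), times = length(config$stages))
    cv <- 0.1
    sdlog <- sqrt(log(1 + cv^2))
    libs <- rlnorm(length(stages),
                   meanlog = log(config$mean_library_size) - sdlog^2 / 2,
                   sdlog = sdlog)
    tibble(
      sample_id = paste0(stages, "_r", reps),
      stage = stages,
      replicate = reps,
      library_size = round(libs)
    )
  })
}
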