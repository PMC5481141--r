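#' Developmental stage vocabulary
#'
#' The eight developmental stages of the oyster MeDIP-seq design, in
#' chronological order from unfertilised oocyte to post-metamorphosis spat.
#' All stage columns and sample sheets in the package use these labels in
#' this order.
#'
#' @return Character vector of the 8 ordered stage labels.
#' @export
#' @examples
#' medip_stages()
medip_stages <- function() {
  c("oocyte", "cells_2_8", "morula", "blastula", "gastrula",
    "trochophore", "dlarva", "spat")
}

#' Mid-larval stages pooled for the intermediate developmental step
#' @return Character vector of the five pooled mid-larval stage labels.
#' @export
medip_midlarval_stages <- function() {
  c("morula", "blastula", "gastrula", "trochophore", "dlarva")
}

#' Two-group design for a developmental step
#'
#' The three developmental transitions at which differential methylation is
#' assessed: cleavage (`"C"`, oocyte vs 2-8 cells), intermediate (`"I"`,
#' 2-8 cells vs the pooled mid-larval stages), and metamorphosis (`"M"`,
#' pooled mid-larval vs spat). Replicates of every stage in a pooled group
#' are treated as samples of that group.
#'
#' @param step One of `"C"`, `"I"`, `"M"`.
#' @return A list with elements `step`, `earlier` (stage labels of the
#'   earlier group) and `later` (stage labels of the later group).
#' @export
#' @examples
#' step_design("C")
#' step_design("M")$earlier
step_design <- function(step = c("C", "I", "M")) {
  step <- match.arg(step)
  mid <- medip_midlarval_stages()
  switch(step,
    C = list(step = "C", earlier = "oocyte", later = "cells_2_8"),
    I = list(step = "I", earlier = "cells_2_8", later = mid),
    M = list(step = "M", earlier = mid, later = "spat")
  )
}

# samples in each group of a step design, in sample-sheet order
design_groups <- function(samples, design) {
  earlier <- samples$sample_id[samples$stage %in% design$earlier]
  later <- samples$sample_id[samples$stage %in% design$later]
  if (length(earlier) < 2L || length(later) < 2L) {
    rlang::abort(sprintf(
      "step '%s' needs at least 2 samples per group (got %d earlier, %d later)",
      design$step, length(earlier), length(later)
    ))
  }
  list(earlier = earlier, later = later)
}
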