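#' Generate a synthetic genome annotation
#'
#' Lays out non-overlapping gene models (one upstream promoter, then
#' alternating CDS and intron parts), repeats and transposable elements on
#' a set of scaffolds by sequential packing with random intergenic gaps.
#' Transposable elements are labelled class I (retrotransposon) with the
#' configured probability, class II (DNA transposon) otherwise. Promoter
#' lengths straddle 100 bp so the promoter-length filter of
#' [read_annotation()] is exercised. Deterministic for a fixed config seed.
#'
#' @param config A [simulation_config()].
#' @return A [medip_annotation()] object.
#' @export
#' @examples
#' ann <- simulate_annotation(simulation_config(n_genes = 20, seed = 1))
#' ann
simulate_annotation <- function(config) {
  with_substream(config$seed, "annotation", {
    n_sc <- config$n_scaffolds
    sc_len <- floor(runif(n_sc, config$scaffold_length_range[1],
                          config$scaffold_length_range[2] + 1))
    scaffolds <- tibble(
      scaffold = sprintf("scaffold_%03d", seq_len(n_sc)),
      length = as.integer(sc_len)
    )

    # pre-draw gene structures
    exr <- config$exons_per_gene
    genes <- purrr::map(seq_len(config$n_genes), function(i) {
      n_ex <- if (exr[1] == exr[2]) exr[1] else sample(exr[1]:exr[2], 1L)
      list(
        gene_id = sprintf("g%04d", i),
        prom = sample(config$promoter_length_range[1]:config$promoter_length_range[2], 1L),
        exons = sample(150:400, n_ex, replace = TRUE),
        introns = if (n_ex > 1) sample(100:800, n_ex - 1L, replace = TRUE) else integer(),
        strand = sample(c("+", "-"), 1L)
      )
    })
    tes <- purrr::map(seq_len(config$n_tes), function(i) {
      list(id = sprintf("te%04d", i), len = sample(200:1500, 1L),
           te_class = if (runif(1) < config$te_class1_fraction) "I" else "II")
    })
    reps <- purrr::map(seq_len(config$n_repeats), function(i) {
      list(id = sprintf("rep%04d", i), len = sample(100:800, 1L))
    })

    # one shuffled queue of cassettes packed across scaffolds in order
    queue <- c(
      purrr::map(genes, ~ c(.x, type = "gene")),
      purrr::map(tes, ~ c(.x, type = "te")),
      purrr::map(reps, ~ c(.x, type = "rep"))
    )
    queue <- queue[sample.int(length(queue))]

    # vector accumulators (one tibble at the end; per-row tibbles are slow)
    cap <- sum(vapply(genes, function(g) 2L * length(g$exons), 1L)) +
      config$n_tes + config$n_repeats
    a_id <- a_sc <- a_cls <- a_gid <- a_tec <- a_str <- character(cap)
    a_s0 <- a_e0 <- integer(cap)
    nrow_used <- 0L
    add_row <- function(eid, sc, s0, e0, cls, gid, tec, str) {
      nrow_used <<- nrow_used + 1L
      a_id[nrow_used] <<- eid
      a_sc[nrow_used] <<- sc
      a_s0[nrow_used] <<- s0
      a_e0[nrow_used] <<- e0
      a_cls[nrow_used] <<- cls
      a_gid[nrow_used] <<- gid
      a_tec[nrow_used] <<- tec
      a_str[nrow_used] <<- str
    }

    # place each cassette on a scaffold drawn with probability proportional
    # to remaining space, so features spread over the whole genome
    pos <- integer(n_sc)
    for (cass in queue) {
      len <- if (cass$type == "gene") {
        cass$prom + sum(cass$exons) + sum(cass$introns)
      } else {
        cass$len
      }
      gap <- sample(200:2000, 1L)
      rem <- sc_len - pos
      ok <- which(rem >= gap + len + 200)
      if (!length(ok)) {
        abort("scaffolds too short to host the requested features; enlarge the genome or reduce feature counts")
      }
      si <- if (length(ok) == 1L) ok else sample(ok, 1L, prob = rem[ok])
      start <- pos[si] + gap
      sc <- scaffolds$scaffold[si]
      if (cass$type == "gene") {
        # layout left-to-right: PRO then CDS1 INT1 CDS2 ... for '+' genes;
        # mirrored for '-' genes (promoter at the right end)
        parts_len <- c(cass$prom,
                       as.vector(rbind(cass$exons,
                                       c(cass$introns, NA)))[!is.na(
                         as.vector(rbind(cass$exons, c(cass$introns, NA))))])
        n_ex <- length(cass$exons)
        part_class <- c("PRO",
                        as.vector(rbind(rep("CDS", n_ex),
                                        c(rep("INT", max(0L, n_ex - 1L)), NA))))
        part_class <- part_class[!is.na(part_class)]
        part_idx <- c(0L, as.vector(rbind(seq_len(n_ex),
                                          c(seq_len(max(0L, n_ex - 1L)), NA))))
        part_idx <- part_idx[!is.na(part_idx)]
        if (cass$strand == "-") {
          parts_len <- rev(parts_len)
          part_class <- rev(part_class)
          part_idx <- rev(part_idx)
        }
        ends <- start + cumsum(parts_len)
        starts <- c(start, head(ends, -1L))
        for (k in seq_along(parts_len)) {
          eid <- if (part_class[k] == "PRO") {
            paste0(cass$gene_id, "_PRO")
          } else {
            sprintf("%s_%s%d", cass$gene_id, part_class[k], part_idx[k])
          }
          add_row(eid, sc, as.integer(starts[k]), as.integer(ends[k]),
                  part_class[k], cass$gene_id, NA_character_, cass$strand)
        }
        pos[si] <- as.integer(start + len)
      } else {
        add_row(cass$id, sc, as.integer(start), as.integer(start + len),
                if (cass$type == "te") "TE" else "REP", NA_character_,
                if (cass$type == "te") cass$te_class else NA_character_,
                sample(c("+", "-"), 1L))
        pos[si] <- as.integer(start + len)
      }
    }

    idx <- seq_len(nrow_used)
    elements <- tibble(
      element_id = a_id[idx], scaffold = a_sc[idx], start = a_s0[idx],
      end = a_e0[idx], feature_class = a_cls[idx],
      gene_id = ifelse(a_gid[idx] == "" | is.na(a_gid[idx]),
                       NA_character_, a_gid[idx]),
      te_class = ifelse(a_tec[idx] == "" | is.na(a_tec[idx]),
                        NA_character_, a_tec[idx]),
      strand = a_str[idx]
    ) |>
      arrange(.data$scaffold, .data$start)
    medip_annotation(scaffolds, elements)
  })
}
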