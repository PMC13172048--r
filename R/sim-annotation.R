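#' Generate synthetic annotation, genome and regulatory elements
#'
#' Lays out one transcript group per gene on a single synthetic chromosome.
#' Genes occupy non-overlapping slots except for designed pairs: divergent
#' non-coding RNAs sit head-to-head with a coding partner (opposite strands,
#' TSSs within 1 kb, pointing away from each other) and antisense non-coding
#' RNAs overlap a coding partner on the opposite strand. A configurable
#' fraction of transcripts receives a promoter-like element (PLS) within
#' 500 bp of its TSS; the remainder have none, forcing promoter imputation
#' downstream. Ground truth (ISG identities, per-treatment true log2 fold
#' changes, single-cell programs, pair regulation) is created here.
#'
#' @param config An [sim_config()] object.
#' @return A list with elements `genome` (named character vector of
#'   chromosome sequences), `transcripts` (tibble of transcript models),
#'   `elements` (tibble of promoter-like elements), and `truth` (ground-truth
#'   list; see Details).
#' @details `truth` carries: `isg_ids`, per-gene `effects`, `true_log2fc`
#'   (long tibble transcript x treatment), `pairs` (ncRNA/coding pair table
#'   with orientation and regulation), `core_ids` and `programs` (per-cell-type
#'   induced gene sets), `heterogeneous_ids`, and a `motif_planted` slot
#'   filled by [plant_motifs()].
#' @export
sim_annotation <- function(config) {
  stopifnot(inherits(config, "ifn_sim_config"))
  n_cod <- config$n_coding_genes
  n_nc <- config$n_noncoding_genes
  n_div <- round(config$frac_divergent_pairs * n_nc)
  n_as <- round(config$frac_antisense_pairs * n_nc)
  n_unpaired <- n_nc - n_div - n_as
  n_slots <- n_cod + n_unpaired
  spacing <- config$gene_spacing
  assert_that(500 + n_slots * spacing + 500 <= config$chrom_length,
              "chromosome too short to place all genes without overlap")

  with_stage_seed(config$seed, "annotation", {
    genome_seq <- intToUtf8(sample(utf8ToInt("ACGT"), config$chrom_length,
                                   replace = TRUE))

    slot_start <- 500 + (seq_len(n_slots) - 1L) * spacing
    slot_owner <- sample(rep(c("coding", "nc"), c(n_cod, n_unpaired)))

    cod_len <- 800L
    nc_len <- 400L
    cod_slots <- slot_start[slot_owner == "coding"]
    cod_strand <- sample(c("+", "-"), n_cod, replace = TRUE)
    cod <- tibble::tibble(
      transcript_id = sprintf("tx_cod_%04d", seq_len(n_cod)),
      gene_id = sprintf("g_cod_%04d", seq_len(n_cod)),
      chrom = config$chrom,
      start = cod_slots + 1100L,
      end = cod_slots + 1100L + cod_len,
      strand = cod_strand,
      biotype = "coding"
    )

    # ISG identities and per-gene true effect sizes (at potency 1)
    n_isg <- round(config$frac_isg * n_cod)
    isg_ids <- sort(sample(cod$transcript_id, n_isg))
    effects <- setNames(rep(0, n_cod), cod$transcript_id)
    # bounded +/-20% per-gene variation keeps every ISG a bona fide responder
    effects[isg_ids] <- config$effect_log2fc * runif(n_isg, 0.8, 1.2)

    # pair partners: regulated pairs need ISG partners, so enrich for them
    n_pair <- n_div + n_as
    partners <- character(0)
    if (n_pair > 0) {
      want_isg <- min(length(isg_ids), round(0.6 * n_pair))
      pool <- c(sample(isg_ids, want_isg),
                sample(setdiff(cod$transcript_id, isg_ids),
                       n_pair - want_isg))
      partners <- sample(pool)
    }

    nc_rows <- list()
    pair_rows <- list()
    nc_idx <- 0L
    add_nc <- function(start, end, strand, biotype) {
      nc_idx <<- nc_idx + 1L
      tibble::tibble(
        transcript_id = sprintf("tx_nc_%04d", nc_idx),
        gene_id = sprintf("g_nc_%04d", nc_idx),
        chrom = config$chrom, start = start, end = end,
        strand = strand, biotype = biotype
      )
    }

    orientations <- rep(c("divergent", "antisense"), c(n_div, n_as))
    for (k in seq_len(n_pair)) {
      p <- cod[cod$transcript_id == partners[[k]], ]
      p_tss <- if (p$strand == "+") p$start else p$end - 1L
      if (orientations[[k]] == "divergent") {
        d <- sample(200:500, 1)
        if (p$strand == "+") {
          q <- p_tss - d                      # nc on -, transcribes leftward
          row <- add_nc(q - nc_len + 1L, q + 1L, "-", "divergent")
        } else {
          q <- p_tss + d                      # nc on +, transcribes rightward
          row <- add_nc(q, q + nc_len, "+", "divergent")
        }
      } else {
        u <- sample(200:600, 1)               # TSS inside the partner body
        if (p$strand == "+") {
          q <- p_tss + u
          row <- add_nc(q - nc_len + 1L, q + 1L, "-", "antisense")
        } else {
          q <- p_tss - u
          row <- add_nc(q, q + nc_len, "+", "antisense")
        }
      }
      nc_rows[[k]] <- row
      pair_rows[[k]] <- tibble::tibble(
        ncrna_id = row$transcript_id, coding_id = p$transcript_id,
        orientation = orientations[[k]]
      )
    }

    nc_slots <- slot_start[slot_owner == "nc"]
    nc_strand_up <- sample(c("+", "-"), n_unpaired, replace = TRUE)
    for (k in seq_len(n_unpaired)) {
      nc_rows[[n_pair + k]] <- add_nc(nc_slots[[k]] + 1300L,
                                      nc_slots[[k]] + 1300L + nc_len,
                                      nc_strand_up[[k]], "lncRNA")
    }

    transcripts <- dplyr::bind_rows(c(list(cod), nc_rows)) %>%
      dplyr::mutate(
        tss = ifelse(.data$strand == "+", .data$start, .data$end - 1L),
        group_id = .data$transcript_id,
        high_confidence = runif(dplyr::n()) < config$frac_high_confidence
      ) %>%
      dplyr::select("transcript_id", "gene_id", "group_id", "chrom",
                    "start", "end", "tss", "strand", "biotype",
                    "high_confidence")

    pairs <- if (n_pair > 0) dplyr::bind_rows(pair_rows) else
      tibble::tibble(ncrna_id = character(), coding_id = character(),
                     orientation = character())

    # pair regulation: co/anti only when the coding partner is a true ISG
    pairs$regulation <- "none"
    if (nrow(pairs) > 0) {
      reg <- pairs$coding_id %in% isg_ids
      anti <- reg & (runif(nrow(pairs)) < config$frac_anticorrelated)
      pairs$regulation[reg] <- "co"
      pairs$regulation[anti] <- "anti"
      eff_nc <- setNames(rep(0, nrow(pairs)), pairs$ncrna_id)
      eff_nc[pairs$regulation == "co"] <-
        effects[pairs$coding_id[pairs$regulation == "co"]]
      eff_nc[pairs$regulation == "anti"] <-
        -effects[pairs$coding_id[pairs$regulation == "anti"]]
      effects <- c(effects, eff_nc)
    }
    all_ids <- transcripts$transcript_id
    effects <- setNames(ifelse(all_ids %in% names(effects),
                               effects[all_ids], 0), all_ids)
    effects[is.na(effects)] <- 0

    true_log2fc <- tidyr::expand_grid(
      transcript_id = all_ids,
      treatment = setdiff(config$treatments, config$mock)
    ) %>%
      dplyr::mutate(true_log2fc = effects[.data$transcript_id] *
                      config$potency[.data$treatment])

    # promoter-like elements; pair members share one PLS decision
    elements <- sim_pls_elements(config, transcripts, pairs)

    # single-cell programs: shared core + per-type specific + heterogeneous
    n_core <- round(config$core_frac * length(isg_ids))
    core_ids <- sort(sample(isg_ids, n_core))
    rest <- sample(setdiff(isg_ids, core_ids))
    type_of <- rep(config$cell_types, length.out = length(rest))
    programs <- lapply(setNames(config$cell_types, config$cell_types),
                       function(ct) sort(c(core_ids, rest[type_of == ct])))
    het_ids <- character(0)
    if (length(rest) > 0 && config$frac_heterogeneous > 0) {
      het_ids <- sort(sample(rest, round(config$frac_heterogeneous *
                                           length(rest))))
    }

    truth <- list(
      isg_ids = isg_ids, effects = effects, true_log2fc = true_log2fc,
      pairs = pairs, core_ids = core_ids, programs = programs,
      heterogeneous_ids = het_ids, motif_planted = NULL
    )
    list(genome = setNames(genome_seq, config$chrom),
         transcripts = transcripts, elements = elements, truth = truth)
  })
}

# One Bernoulli(frac_pls) per "promoter unit": unpaired transcripts draw
# individually; pair members draw jointly so a no-PLS transcript is never
# rescued by its partner's element (divergent partners share one element
# midway between the TSSs, antisense partners get one element each).
sim_pls_elements <- function(config, transcripts, pairs) {
  paired_nc <- pairs$ncrna_id
  paired_cod <- pairs$coding_id
  singles <- setdiff(transcripts$transcript_id, c(paired_nc, paired_cod))
  width <- 200L
  rows <- list()
  eid <- 0L
  add_el <- function(center) {
    eid <<- eid + 1L
    start <- max(0L, as.integer(center) - width %/% 2L)
    tibble::tibble(element_id = sprintf("pls_%05d", eid),
                   chrom = config$chrom, start = start,
                   end = start + width)
  }
  tss_of <- setNames(transcripts$tss, transcripts$transcript_id)

  keep_single <- runif(length(singles)) < config$frac_pls
  for (id in singles[keep_single]) {
    rows[[length(rows) + 1L]] <- add_el(tss_of[[id]] + sample(-150:150, 1))
  }
  if (nrow(pairs) > 0) {
    keep_pair <- runif(nrow(pairs)) < config$frac_pls
    for (k in which(keep_pair)) {
      t_nc <- tss_of[[pairs$ncrna_id[[k]]]]
      t_cd <- tss_of[[pairs$coding_id[[k]]]]
      if (pairs$orientation[[k]] == "divergent") {
        rows[[length(rows) + 1L]] <- add_el((t_nc + t_cd) / 2)
      } else {
        rows[[length(rows) + 1L]] <- add_el(t_cd + sample(-150:150, 1))
        rows[[length(rows) + 1L]] <- add_el(t_nc + sample(-150:150, 1))
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(element_id = character(), chrom = character(),
                          start = integer(), end = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$start)
}
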