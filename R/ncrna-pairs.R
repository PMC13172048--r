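#' Pair divergent non-coding RNAs with coding neighbours
#'
#' A non-coding transcript is divergent-paired with a protein-coding
#' transcript when the two lie on opposite strands in head-to-head
#' orientation (TSSs pointing away from each other: the minus-strand TSS at
#' or left of the plus-strand TSS) with TSS distance at most `max_tss_gap`.
#' When several coding transcripts qualify, the nearest TSS wins.
#' `mode = "name"` instead pairs by gene-name suffix ("-AS1"/"-DT"
#' convention).
#'
#' @param annotation Transcript models tibble (`transcript_id`, `gene_id`,
#'   `chrom`, `start`, `end`, `tss`, `strand`, `biotype`).
#' @param max_tss_gap Maximum TSS-to-TSS distance in bp.
#' @param mode `"geometry"` (default) or `"name"`.
#' @return Tibble `ncrna_id`, `coding_id`, `orientation = "divergent"`,
#'   `tss_distance`.
#' @export
pair_divergent <- function(annotation, max_tss_gap = 1000,
                           mode = c("geometry", "name")) {
  mode <- match.arg(mode)
  assert_columns(annotation, c("transcript_id", "chrom", "tss", "strand",
                               "biotype"), "annotation")
  nc <- dplyr::filter(annotation, .data$biotype != "coding")
  cod <- dplyr::filter(annotation, .data$biotype == "coding")
  if (mode == "name") {
    return(pair_by_name(annotation, suffixes = c("-DT", "-AS1"),
                        orientation = "divergent"))
  }
  cand <- dplyr::inner_join(
    dplyr::select(nc, ncrna_id = "transcript_id", "chrom",
                  nc_tss = "tss", nc_strand = "strand"),
    dplyr::select(cod, coding_id = "transcript_id", "chrom",
                  cod_tss = "tss", cod_strand = "strand"),
    by = "chrom", relationship = "many-to-many"
  ) %>%
    dplyr::filter(.data$nc_strand != .data$cod_strand) %>%
    dplyr::mutate(
      minus_tss = ifelse(.data$nc_strand == "-", .data$nc_tss, .data$cod_tss),
      plus_tss = ifelse(.data$nc_strand == "-", .data$cod_tss, .data$nc_tss),
      tss_distance = abs(.data$nc_tss - .data$cod_tss)
    ) %>%
    dplyr::filter(.data$minus_tss <= .data$plus_tss,
                  .data$tss_distance <= max_tss_gap)
  cand %>%
    dplyr::group_by(.data$ncrna_id) %>%
    dplyr::slice_min(.data$tss_distance, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup() %>%
    dplyr::transmute(.data$ncrna_id, .data$coding_id,
                     orientation = "divergent", .data$tss_distance)
}

#' Pair antisense non-coding RNAs with overlapping coding transcripts
#'
#' A non-coding transcript is antisense-paired with a coding transcript when
#' the two overlap by at least one base on opposite strands; the coding
#' partner with the largest overlap wins ties.
#'
#' @inheritParams pair_divergent
#' @return Tibble `ncrna_id`, `coding_id`, `orientation = "antisense"`,
#'   `overlap_bp`.
#' @export
pair_antisense <- function(annotation, mode = c("geometry", "name")) {
  mode <- match.arg(mode)
  assert_columns(annotation, c("transcript_id", "chrom", "start", "end",
                               "strand", "biotype"), "annotation")
  if (mode == "name") {
    return(pair_by_name(annotation, suffixes = "-AS1",
                        orientation = "antisense"))
  }
  nc <- dplyr::filter(annotation, .data$biotype != "coding")
  cod <- dplyr::filter(annotation, .data$biotype == "coding")
  dplyr::inner_join(
    dplyr::select(nc, ncrna_id = "transcript_id", "chrom",
                  nc_start = "start", nc_end = "end", nc_strand = "strand"),
    dplyr::select(cod, coding_id = "transcript_id", "chrom",
                  cod_start = "start", cod_end = "end",
                  cod_strand = "strand"),
    by = "chrom", relationship = "many-to-many"
  ) %>%
    dplyr::filter(.data$nc_strand != .data$cod_strand) %>%
    dplyr::mutate(overlap_bp = pmin(.data$nc_end, .data$cod_end) -
                    pmax(.data$nc_start, .data$cod_start)) %>%
    dplyr::filter(.data$overlap_bp >= 1) %>%
    dplyr::group_by(.data$ncrna_id) %>%
    dplyr::slice_max(.data$overlap_bp, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup() %>%
    dplyr::transmute(.data$ncrna_id, .data$coding_id,
                     orientation = "antisense", .data$overlap_bp)
}

pair_by_name <- function(annotation, suffixes, orientation) {
  assert_columns(annotation, c("transcript_id", "gene_id", "biotype"),
                 "annotation")
  nc <- dplyr::filter(annotation, .data$biotype != "coding")
  cod <- dplyr::filter(annotation, .data$biotype == "coding")
  pattern <- paste0("(", paste(suffixes, collapse = "|"), ")$")
  nc %>%
    dplyr::filter(stringr::str_detect(.data$gene_id, pattern)) %>%
    dplyr::mutate(base = stringr::str_remove(.data$gene_id, pattern)) %>%
    dplyr::inner_join(dplyr::select(cod, coding_id = "transcript_id",
                                    base = "gene_id"), by = "base") %>%
    dplyr::transmute(ncrna_id = .data$transcript_id, .data$coding_id,
                     orientation = .env$orientation)
}

#' Classify joint regulation of ncRNA / coding pairs
#'
#' For each pair whose ncRNA is a DET in a contrast: the pair is
#' `co-regulated` when the coding partner is a DET with the same sign,
#' `anticorrelated` with opposite signs, and `unmatched-coding-not-DE` when
#' the coding partner is not a DET. Pairs whose ncRNA is not a DET in the
#' contrast get `NA`. A cross-contrast summary (`classification_any`) marks a
#' pair anticorrelated if any shared-DET contrast shows opposite signs, else
#' co-regulated.
#'
#' @param pairs Tibble `ncrna_id`, `coding_id` (plus any extra columns).
#' @param det_sets Named list, contrast -> [det_filter()] result.
#' @return A list with `per_contrast` (tibble `ncrna_id`, `coding_id`,
#'   `contrast`, `classification`) and `summary` (one row per pair with
#'   `classification_any`).
#' @export
classify_pairs <- function(pairs, det_sets) {
  assert_columns(pairs, c("ncrna_id", "coding_id"), "pairs")
  assert_that(length(det_sets) >= 1 && !is.null(names(det_sets)),
              "`det_sets` must be a named list of det_filter() results")
  per <- purrr::imap_dfr(det_sets, function(ds, contrast) {
    sign_of <- function(ids) {
      dplyr::case_when(ids %in% ds$up ~ 1, ids %in% ds$down ~ -1,
                       TRUE ~ 0)
    }
    nc_sign <- sign_of(pairs$ncrna_id)
    cod_sign <- sign_of(pairs$coding_id)
    tibble::tibble(
      ncrna_id = pairs$ncrna_id, coding_id = pairs$coding_id,
      contrast = contrast,
      classification = dplyr::case_when(
        nc_sign == 0 ~ NA_character_,
        cod_sign == 0 ~ "unmatched-coding-not-DE",
        nc_sign == cod_sign ~ "co-regulated",
        TRUE ~ "anticorrelated"
      )
    )
  })
  summary <- per %>%
    dplyr::filter(!is.na(.data$classification)) %>%
    dplyr::group_by(.data$ncrna_id, .data$coding_id) %>%
    dplyr::summarise(
      classification_any = dplyr::case_when(
        any(.data$classification == "anticorrelated") ~ "anticorrelated",
        any(.data$classification == "co-regulated") ~ "co-regulated",
        TRUE ~ "unmatched-coding-not-DE"
      ),
      n_det_contrasts = dplyr::n(), .groups = "drop"
    )
  list(per_contrast = per, summary = summary)
}
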