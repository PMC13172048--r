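#' Match transcripts to promoter-like elements near their TSS
#'
#' A transcript matches an element when the distance from its TSS to the
#' nearest base of the element is at most `max_gap` (0 when the TSS lies
#' inside the element). When several elements qualify for one TSS, all are
#' retained; the result is many-to-many.
#'
#' @param transcripts Tibble with columns `transcript_id`, `chrom`, `tss`.
#' @param elements Tibble with columns `element_id`, `chrom`, `start`, `end`
#'   (0-based, half-open).
#' @param max_gap Maximum TSS-to-element-edge distance in bp (boundary
#'   inclusive).
#' @return Tibble `transcript_id`, `element_id`, `gap`.
#' @export
#' @examples
#' tx <- tibble::tibble(transcript_id = "t1", chrom = "chr1", tss = 10000)
#' el <- tibble::tibble(element_id = "e1", chrom = "chr1",
#'                      start = 10300, end = 10500)
#' match_pls(tx, el)  # gap 300 -> matched
match_pls <- function(transcripts, elements, max_gap = 500) {
  assert_columns(transcripts, c("transcript_id", "chrom", "tss"),
                 "transcripts")
  assert_columns(elements, c("element_id", "chrom", "start", "end"),
                 "elements")
  assert_that(all(elements$start < elements$end),
              "elements must satisfy start < end")
  if (nrow(transcripts) > 0 && nrow(elements) > 0) {
    bad_el <- setdiff(elements$chrom, transcripts$chrom)
    assert_that(length(bad_el) == 0,
                sprintf("unknown chromosome in elements: %s (%s)",
                        bad_el[1],
                        elements$element_id[elements$chrom == bad_el[1]][1]))
  }
  if (nrow(elements) == 0 || nrow(transcripts) == 0) {
    return(tibble::tibble(transcript_id = character(),
                          element_id = character(), gap = numeric()))
  }
  dplyr::inner_join(
    dplyr::select(transcripts, "transcript_id", "chrom", "tss"),
    dplyr::select(elements, "element_id", "chrom", "start", "end"),
    by = "chrom", relationship = "many-to-many"
  ) %>%
    dplyr::mutate(gap = pmax(0, .data$start - .data$tss,
                             .data$tss - (.data$end - 1))) %>%
    dplyr::filter(.data$gap <= max_gap) %>%
    dplyr::select("transcript_id", "element_id", "gap")
}

#' Extend or trim a region to a fixed length about its midpoint
#'
#' The midpoint is `floor((start + end) / 2)` and the new start is
#' `midpoint - floor(target_len / 2)`; regions overrunning a chromosome edge
#' are shifted inward, preserving length. Vectorised over rows.
#'
#' @param region Tibble with columns `start`, `end` (0-based half-open).
#' @param target_len Output length in bp.
#' @param chrom_len Chromosome length in bp.
#' @return The region tibble with recomputed `start`, `end`.
#' @export
#' @examples
#' extend_region(tibble::tibble(start = 100, end = 300), 350, 10000)
extend_region <- function(region, target_len = 350, chrom_len) {
  assert_columns(region, c("start", "end"), "region")
  assert_that(all(target_len <= chrom_len),
              "target_len exceeds chromosome length")
  mid <- (region$start + region$end) %/% 2
  new_start <- mid - target_len %/% 2
  new_start <- pmax(0, pmin(new_start, chrom_len - target_len))
  region$start <- as.integer(new_start)
  region$end <- as.integer(new_start + target_len)
  region
}

#' Impute a fixed-length promoter centred on the TSS
#'
#' Used for transcripts without a matched promoter-like element: the promoter
#' is the `target_len` bp window centred on the TSS (strand-agnostic),
#' shifted inward at chromosome edges.
#'
#' @param transcript One-row tibble (or tibble of rows) with columns
#'   `transcript_id`, `chrom`, `tss`.
#' @param chrom_len Chromosome length in bp.
#' @param target_len Promoter length in bp.
#' @return Tibble with `chrom`, `start`, `end`, `source = "imputed"`,
#'   `transcript_id`.
#' @export
impute_promoter <- function(transcript, chrom_len, target_len = 350) {
  assert_columns(transcript, c("transcript_id", "chrom", "tss"), "transcript")
  assert_that(all(chrom_len >= target_len),
              sprintf("chromosome shorter than %d bp", target_len))
  start <- pmax(0, pmin(transcript$tss - target_len %/% 2,
                        chrom_len - target_len))
  tibble::tibble(
    chrom = transcript$chrom,
    start = as.integer(start), end = as.integer(start + target_len),
    source = "imputed", transcript_id = transcript$transcript_id
  )
}

#' Assign every transcript at least one fixed-length promoter region
#'
#' Matched promoter-like elements (within `max_gap` of the TSS) are extended
#' to `target_len` about their midpoint; transcripts with no match get one
#' imputed promoter centred on the TSS. Identical regions serving multiple
#' transcripts are merged, pooling their transcript ids.
#'
#' @param transcripts Tibble of transcript models (`transcript_id`, `chrom`,
#'   `tss`, ...).
#' @param elements Tibble of promoter-like elements.
#' @param chrom_len Chromosome length(s): a single number or a named vector
#'   keyed by chromosome.
#' @param max_gap Maximum TSS-to-element distance for a match.
#' @param target_len Uniform promoter length.
#' @return Tibble `promoter_id`, `chrom`, `start`, `end`, `source`
#'   (`matched`/`imputed`), `element_id` (comma-joined, `NA` for imputed),
#'   `transcript_ids` (list column).
#' @export
assign_promoters <- function(transcripts, elements, chrom_len,
                             max_gap = 500, target_len = 350) {
  assert_columns(transcripts, c("transcript_id", "chrom", "tss"),
                 "transcripts")
  len_of <- function(chrom) {
    if (length(chrom_len) == 1 && is.null(names(chrom_len))) {
      rep(unname(chrom_len), length(chrom))
    } else {
      assert_that(all(chrom %in% names(chrom_len)),
                  "chrom_len must name every chromosome")
      unname(chrom_len[chrom])
    }
  }

  matches <- match_pls(transcripts, elements, max_gap = max_gap)
  matched <- dplyr::inner_join(
    matches, dplyr::select(elements, "element_id", "chrom", "start", "end"),
    by = "element_id"
  )
  regions <- list()
  if (nrow(matched) > 0) {
    ext <- extend_region(matched, target_len = target_len,
                         chrom_len = len_of(matched$chrom))
    regions$matched <- tibble::tibble(
      chrom = ext$chrom, start = ext$start, end = ext$end,
      source = "matched", transcript_id = ext$transcript_id,
      element_id = ext$element_id
    )
  }
  unmatched <- dplyr::filter(transcripts,
                             !.data$transcript_id %in% matches$transcript_id)
  if (nrow(unmatched) > 0) {
    imp <- impute_promoter(unmatched, chrom_len = len_of(unmatched$chrom),
                           target_len = target_len)
    imp$element_id <- NA_character_
    regions$imputed <- imp
  }
  all_regions <- dplyr::bind_rows(regions)
  out <- all_regions %>%
    dplyr::group_by(.data$chrom, .data$start, .data$end) %>%
    dplyr::summarise(
      source = if (any(.data$source == "matched")) "matched" else "imputed",
      element_id = if (all(is.na(.data$element_id))) NA_character_ else
        paste(sort(unique(stats::na.omit(.data$element_id))), collapse = ","),
      transcript_ids = list(sort(unique(.data$transcript_id))),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$chrom, .data$start) %>%
    dplyr::mutate(promoter_id = sprintf("%s:%d-%d", .data$chrom,
                                        .data$start, .data$end)) %>%
    dplyr::select("promoter_id", "chrom", "start", "end", "source",
                  "element_id", "transcript_ids")
  covered <- unique(unlist(out$transcript_ids))
  assert_that(setequal(covered, transcripts$transcript_id),
              "internal error: some transcripts have no promoter")
  out
}
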