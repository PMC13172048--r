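#' Standardise raw motif scores against a reference promoter set
#'
#' Z-normalises each PWM's scores using the mean and standard deviation
#' (denominator `n - 1` by default) computed over the reference promoters —
#' those matched to high-confidence transcripts.
#'
#' @param scores Numeric matrix, promoters (rows, named) x PWMs (columns).
#' @param reference_ids Row names forming the reference set (>= 2).
#' @param sd_denominator `"n-1"` (sample SD, default) or `"n"`.
#' @return Matrix of z-scores with the same dimensions and names.
#' @export
reference_standardise <- function(scores, reference_ids,
                                  sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  scores <- as.matrix(scores)
  assert_that(!is.null(rownames(scores)), "`scores` must have row names")
  missing <- setdiff(reference_ids, rownames(scores))
  assert_that(length(missing) == 0,
              sprintf("reference id(s) missing from scores: %s",
                      paste(head(missing, 3), collapse = ", ")))
  assert_that(length(reference_ids) >= 2, "need >= 2 reference promoters")
  ref <- scores[reference_ids, , drop = FALSE]
  mu <- colMeans(ref)
  sigma <- apply(ref, 2, sd)
  if (sd_denominator == "n") {
    n <- length(reference_ids)
    sigma <- sigma * sqrt((n - 1) / n)
  }
  zero <- which(!is.finite(sigma) | sigma == 0)
  assert_that(length(zero) == 0,
              sprintf("zero reference variance for PWM(s): %s",
                      paste(colnames(scores)[zero], collapse = ", ")))
  sweep(sweep(scores, 2, mu, "-"), 2, sigma, "/")
}

#' Per-promoter motif-cluster scores
#'
#' Sums the standardised scores of all PWMs within each cluster and
#' Z-standardises the sums again against the same reference promoter set,
#' yielding the final per-promoter cluster score.
#'
#' @param z Matrix of per-PWM z-scores (promoters x PWMs) from
#'   [reference_standardise()].
#' @param clusters Tibble `pwm_id`, `cluster_id` partitioning the PWM set.
#' @param reference_ids Reference promoter ids.
#' @return Matrix, promoters x clusters.
#' @export
cluster_scores <- function(z, clusters, reference_ids) {
  assert_columns(clusters, c("pwm_id", "cluster_id"), "clusters")
  assert_that(setequal(clusters$pwm_id, colnames(z)) &&
                !anyDuplicated(clusters$pwm_id),
              "`clusters` must partition the PWM set (each PWM exactly once)")
  assert_that(all(table(clusters$cluster_id) >= 1), "empty cluster")
  ids <- sort(unique(clusters$cluster_id))
  sums <- vapply(ids, function(cl) {
    members <- clusters$pwm_id[clusters$cluster_id == cl]
    rowSums(z[, members, drop = FALSE])
  }, numeric(nrow(z)))
  dimnames(sums) <- list(rownames(z), ids)
  reference_standardise(sums, reference_ids)
}

#' Per-transcript cluster scores
#'
#' Each transcript group is assigned the maximum cluster score over all of
#' its associated promoters.
#'
#' @param cluster_z Matrix, promoters x clusters, from [cluster_scores()].
#' @param promoter_map Tibble `promoter_id`, `transcript_id` (one row per
#'   promoter-transcript link).
#' @return Tibble `transcript_id`, `cluster_id`, `score`.
#' @export
transcript_cluster_scores <- function(cluster_z, promoter_map) {
  assert_columns(promoter_map, c("promoter_id", "transcript_id"),
                 "promoter_map")
  missing <- setdiff(promoter_map$promoter_id, rownames(cluster_z))
  assert_that(length(missing) == 0,
              sprintf("promoter(s) missing from score table: %s",
                      paste(head(missing, 3), collapse = ", ")))
  tibble::as_tibble(cluster_z, rownames = "promoter_id") %>%
    tidyr::pivot_longer(-"promoter_id", names_to = "cluster_id",
                        values_to = "score") %>%
    dplyr::inner_join(promoter_map, by = "promoter_id",
                      relationship = "many-to-many") %>%
    dplyr::group_by(.data$transcript_id, .data$cluster_id) %>%
    dplyr::summarise(score = max(.data$score), .groups = "drop")
}

#' Score promoters against a PWM library and aggregate to transcripts
#'
#' Runs the full motif-scoring stage: extracts promoter sequences from the
#' genome, computes each promoter's maximum log-odds score per PWM over both
#' strands, Z-standardises raw scores against the reference promoters (those
#' whose transcript set contains at least one high-confidence transcript),
#' aggregates PWM z-scores into motif-cluster scores (re-standardised), and
#' assigns each transcript the maximum cluster score over its promoters.
#'
#' @param promoters Tibble from [assign_promoters()].
#' @param genome Named character vector of chromosome sequences.
#' @param library An `ifn_motif_library`, or a list with `pwms` (named list
#'   of 4 x W count matrices) and `clusters` (tibble `pwm_id`, `cluster_id`).
#' @param transcripts Transcript models carrying `high_confidence`.
#' @param background,pseudocount Passed to [pwm_log_odds()].
#' @return An object of class `ifn_promoter_scores`: list with `raw` and `z`
#'   (promoters x PWMs matrices), `cluster_z` (promoters x clusters),
#'   `transcript_scores` (tibble), `reference_ids`, and `promoter_map`.
#' @export
score_promoters <- function(promoters, genome, library, transcripts,
                            background = rep(0.25, 4), pseudocount = 0.01) {
  assert_columns(promoters, c("promoter_id", "chrom", "start", "end",
                              "transcript_ids"), "promoters")
  assert_columns(transcripts, c("transcript_id", "high_confidence"),
                 "transcripts")
  seqs <- extract_sequences(genome, promoters)
  raw <- vapply(library$pwms, function(pwm) {
    scan_pwm_cpp(unname(seqs), pwm_log_odds(pwm, background, pseudocount))$score
  }, numeric(length(seqs)))
  rownames(raw) <- names(seqs)

  hc <- transcripts$transcript_id[transcripts$high_confidence]
  is_ref <- vapply(promoters$transcript_ids,
                   function(ids) any(ids %in% hc), logical(1))
  reference_ids <- promoters$promoter_id[is_ref]
  assert_that(length(reference_ids) >= 2,
              "fewer than 2 reference (high-confidence) promoters")

  z <- reference_standardise(raw, reference_ids)
  cz <- cluster_scores(z, library$clusters, reference_ids)
  promoter_map <- promoters %>%
    dplyr::select("promoter_id", "transcript_ids") %>%
    tidyr::unnest_longer("transcript_ids", values_to = "transcript_id")
  ts <- transcript_cluster_scores(cz, promoter_map)
  structure(list(raw = raw, z = z, cluster_z = cz, transcript_scores = ts,
                 reference_ids = reference_ids, promoter_map = promoter_map),
            class = "ifn_promoter_scores")
}

#' @export
print.ifn_promoter_scores <- function(x, ...) {
  cat(sprintf(paste0("<ifn_promoter_scores> %d promoters x %d PWMs ",
                     "(%d clusters), %d reference promoters\n"),
              nrow(x$raw), ncol(x$raw), ncol(x$cluster_z),
              length(x$reference_ids)))
  invisible(x)
}

#' @rdname score_promoters
#' @param x An `ifn_promoter_scores` object.
#' @param ... Unused.
#' @export
tidy.ifn_promoter_scores <- function(x, ...) {
  raw_long <- tibble::as_tibble(x$raw, rownames = "promoter_id") %>%
    tidyr::pivot_longer(-"promoter_id", names_to = "pwm_id",
                        values_to = "raw")
  z_long <- tibble::as_tibble(x$z, rownames = "promoter_id") %>%
    tidyr::pivot_longer(-"promoter_id", names_to = "pwm_id",
                        values_to = "z")
  dplyr::inner_join(raw_long, z_long, by = c("promoter_id", "pwm_id"))
}

# Extract promoter sequences (uppercase) from a named genome vector.
extract_sequences <- function(genome, regions) {
  assert_that(all(regions$chrom %in% names(genome)),
              "region chromosome missing from genome")
  lens <- nchar(genome)[regions$chrom]
  assert_that(all(regions$start >= 0) && all(regions$end <= lens),
              "region outside chromosome bounds")
  seqs <- toupper(substring(genome[regions$chrom], regions$start + 1,
                            regions$end))
  setNames(seqs, regions$promoter_id)
}
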