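#' Partition transcripts into likely regulated / unregulated sets
#'
#' Transcripts with motif-cluster z-score at or above `hi` form the "likely
#' regulated" set and those at or below `lo` the "likely unregulated" set;
#' transcripts between the thresholds belong to neither (both boundaries
#' inclusive).
#'
#' @param scores Tibble `transcript_id`, `score` (one cluster's transcript
#'   scores), or a named numeric vector.
#' @param hi,lo Upper and lower z thresholds.
#' @return List with `regulated` and `unregulated` character vectors.
#' @export
partition_transcripts <- function(scores, hi = 2, lo = -1) {
  assert_that(hi > lo, "`hi` must exceed `lo`")
  if (is.numeric(scores)) {
    scores <- tibble::tibble(transcript_id = names(scores), score = scores)
  }
  assert_columns(scores, c("transcript_id", "score"), "scores")
  assert_that(all(is.finite(scores$score)), "scores must be finite")
  list(regulated = scores$transcript_id[scores$score >= hi],
       unregulated = scores$transcript_id[scores$score <= lo])
}

#' Filter transcripts by robust expression
#'
#' Keeps a transcript when its median TPM over the mock samples, or over the
#' treated samples, reaches `threshold` (boundary inclusive).
#'
#' @param tpm Tibble with `transcript_id` and one column per sample.
#' @param treatment_samples,mock_samples Sample column names of the two arms.
#' @param threshold Median TPM cut-off.
#' @return Character vector of retained transcript ids.
#' @export
filter_expressed <- function(tpm, treatment_samples, mock_samples,
                             threshold = 10) {
  assert_columns(tpm, c("transcript_id", treatment_samples, mock_samples),
                 "tpm")
  assert_that(length(treatment_samples) >= 1 && length(mock_samples) >= 1,
              "need >= 1 sample per arm")
  med <- function(cols) {
    apply(as.matrix(tpm[, cols, drop = FALSE]), 1, median)
  }
  keep <- med(mock_samples) >= threshold | med(treatment_samples) >= threshold
  tpm$transcript_id[keep]
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples with midranks for ties. The p-value is
#' exact (by enumeration) when both samples have at most eight observations
#' and there are no ties, and otherwise uses the normal approximation with
#' tie and continuity corrections.
#'
#' @param values_a,values_b Numeric vectors (both non-empty).
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A list with `U` (the statistic for `values_a`) and `p`.
#' @export
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))$p  # exact two-sided: 0.1
mann_whitney_u <- function(values_a, values_b,
                           alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  assert_that(length(values_a) >= 1 && length(values_b) >= 1,
              "both samples must be non-empty")
  assert_that(is.numeric(values_a) && is.numeric(values_b) &&
                all(is.finite(c(values_a, values_b))),
              "samples must be finite numeric vectors")
  no_ties <- !any(duplicated(c(values_a, values_b)))
  exact <- length(values_a) <= 8 && length(values_b) <= 8 && no_ties
  ht <- suppressWarnings(
    wilcox.test(values_a, values_b, alternative = alternative,
                exact = exact, correct = TRUE)
  )
  list(U = unname(ht$statistic), p = min(1, ht$p.value))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false discovery rate correction; adjusted values are capped at 1
#' and returned in the input order.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]` (NAs are propagated
#'   and do not count toward the number of tests).
#' @return Adjusted p-values.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(pvals) {
  ok <- is.na(pvals) | (pvals >= 0 & pvals <= 1)
  assert_that(all(ok), "p-values must lie in [0, 1]")
  p.adjust(pvals, method = "BH")
}

#' Motif-cluster association with IFN-induced fold changes
#'
#' For each motif cluster and each treatment contrast: restricts to robustly
#' expressed transcripts ([filter_expressed()]), partitions them by the
#' cluster's transcript z-scores into likely regulated (z >= `hi`) and likely
#' unregulated (z <= `lo`) sets, and compares the observed log2 fold changes
#' of the two sets with a Mann-Whitney U test. P-values are adjusted by
#' Benjamini-Hochberg over the whole cluster x treatment result set (or per
#' treatment with `bh_pool = "per_treatment"`). Tests with an empty arm are
#' emitted with NA statistics and excluded from the adjustment.
#'
#' @param de Differential table: tibble `transcript_id`, `log2fc`, `contrast`.
#' @param tpm Tibble `transcript_id` plus sample columns.
#' @param samples Tibble `sample_id`, `treatment` describing `tpm`'s columns.
#' @param transcript_scores Tibble `transcript_id`, `cluster_id`, `score`
#'   from [transcript_cluster_scores()].
#' @param mock Label of the mock treatment in `samples`.
#' @param hi,lo Partition thresholds (z units).
#' @param min_tpm Median-TPM expression threshold.
#' @param bh_pool `"global"` (default) or `"per_treatment"`.
#' @return Tibble of class `ifn_association`: `cluster_id`, `treatment`,
#'   `n_regulated`, `n_unregulated`, `U`, `p`, `padj`,
#'   `median_fc_regulated`, `median_fc_unregulated`.
#' @export
run_motif_association <- function(de, tpm, samples, transcript_scores,
                                  mock = "mock", hi = 2, lo = -1,
                                  min_tpm = 10,
                                  bh_pool = c("global", "per_treatment")) {
  bh_pool <- match.arg(bh_pool)
  assert_columns(de, c("transcript_id", "log2fc", "contrast"), "de")
  assert_columns(samples, c("sample_id", "treatment"), "samples")
  assert_columns(transcript_scores, c("transcript_id", "cluster_id", "score"),
                 "transcript_scores")
  treatments <- sort(unique(de$contrast))
  mock_samples <- samples$sample_id[samples$treatment == mock]
  assert_that(length(mock_samples) >= 1, "no mock samples found")

  res <- purrr::map_dfr(treatments, function(tr) {
    tr_samples <- samples$sample_id[samples$treatment == tr]
    expressed <- filter_expressed(tpm, tr_samples, mock_samples,
                                  threshold = min_tpm)
    fc <- de %>%
      dplyr::filter(.data$contrast == tr,
                    .data$transcript_id %in% expressed)
    if (nrow(fc) == 0) {
      warn(sprintf("no expressed transcripts for contrast %s", tr))
      return(NULL)
    }
    fc_of <- setNames(fc$log2fc, fc$transcript_id)
    transcript_scores %>%
      dplyr::filter(.data$transcript_id %in% names(fc_of)) %>%
      dplyr::group_by(.data$cluster_id) %>%
      dplyr::group_modify(function(d, key) {
        part <- partition_transcripts(d, hi = hi, lo = lo)
        a <- fc_of[part$regulated]
        b <- fc_of[part$unregulated]
        if (length(a) == 0 || length(b) == 0) {
          return(tibble::tibble(
            treatment = tr, n_regulated = length(a),
            n_unregulated = length(b), U = NA_real_, p = NA_real_,
            median_fc_regulated = if (length(a)) median(a) else NA_real_,
            median_fc_unregulated = if (length(b)) median(b) else NA_real_
          ))
        }
        mw <- mann_whitney_u(a, b)
        tibble::tibble(
          treatment = tr, n_regulated = length(a),
          n_unregulated = length(b), U = mw$U, p = mw$p,
          median_fc_regulated = median(a), median_fc_unregulated = median(b)
        )
      }) %>%
      dplyr::ungroup()
  })
  if (nrow(res) == 0) {
    warn("no transcripts passed the expression filter for any contrast")
    return(structure(tibble::tibble(), class = c("ifn_association",
                                                 class(tibble::tibble()))))
  }
  res <- if (bh_pool == "global") {
    dplyr::mutate(res, padj = bh_adjust(.data$p))
  } else {
    res %>%
      dplyr::group_by(.data$treatment) %>%
      dplyr::mutate(padj = bh_adjust(.data$p)) %>%
      dplyr::ungroup()
  }
  res <- dplyr::relocate(res, "cluster_id", "treatment", "n_regulated",
                         "n_unregulated", "U", "p", "padj")
  class(res) <- c("ifn_association", class(tibble::tibble()))
  res
}

#' @rdname run_motif_association
#' @param x An `ifn_association` table.
#' @param ... Unused.
#' @export
glance.ifn_association <- function(x, ...) {
  tibble::tibble(
    n_tests = sum(!is.na(x$p)),
    n_significant = sum(x$padj <= 0.05, na.rm = TRUE),
    top_cluster = if (any(!is.na(x$padj))) {
      x$cluster_id[which.min(x$padj)]
    } else NA_character_
  )
}
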