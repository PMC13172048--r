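#' Filter features by robust read support
#'
#' Keeps a feature when there is at least one condition in which every sample
#' has at least `min_reads` assigned reads.
#'
#' @param counts Tibble with `transcript_id` (or `feature_id`) plus one column
#'   per sample.
#' @param conditions Named character vector mapping sample column names to
#'   condition labels.
#' @param min_reads Per-sample count threshold (boundary inclusive).
#' @return Character vector of retained feature ids.
#' @export
filter_robust_bulk <- function(counts, conditions, min_reads = 20) {
  id_col <- intersect(c("transcript_id", "feature_id"), names(counts))[1]
  assert_that(!is.na(id_col), "`counts` needs a transcript_id/feature_id column")
  sample_cols <- setdiff(names(counts), id_col)
  unlabelled <- setdiff(sample_cols, names(conditions))
  assert_that(length(unlabelled) == 0,
              sprintf("unlabelled sample(s): %s",
                      paste(head(unlabelled, 3), collapse = ", ")))
  m <- as.matrix(counts[, sample_cols, drop = FALSE])
  keep <- Reduce(`|`, lapply(unique(conditions[sample_cols]), function(cond) {
    cols <- sample_cols[conditions[sample_cols] == cond]
    apply(m[, cols, drop = FALSE] >= min_reads, 1, all)
  }))
  counts[[id_col]][keep]
}

#' Differentially expressed feature sets at fixed thresholds
#'
#' Splits a differential table into up- and down-regulated sets using
#' `padj <= padj_max` and `|log2fc| >= min_abs_log2fc` (both boundaries
#' inclusive). Features with missing adjusted p-values are excluded and
#' counted.
#'
#' @param de Tibble with `feature_id` (or `transcript_id`), `log2fc`, `padj`,
#'   for one contrast.
#' @param padj_max Adjusted-p threshold.
#' @param min_abs_log2fc Absolute log2 fold-change threshold (0.585 is a
#'   1.5-fold change).
#' @return List of class `ifn_det_set`: `up`, `down` (character vectors),
#'   `n_missing_padj`, and the thresholds used.
#' @export
det_filter <- function(de, padj_max = 0.05, min_abs_log2fc = 0.585) {
  id_col <- intersect(c("feature_id", "transcript_id"), names(de))[1]
  assert_that(!is.na(id_col), "`de` needs a feature_id/transcript_id column")
  assert_columns(de, c("log2fc", "padj"), "de")
  missing <- is.na(de$padj)
  ok <- de[!missing, ]
  sig <- ok$padj <= padj_max
  structure(list(
    up = ok[[id_col]][sig & ok$log2fc >= min_abs_log2fc],
    down = ok[[id_col]][sig & ok$log2fc <= -min_abs_log2fc],
    n_missing_padj = sum(missing),
    padj_max = padj_max, min_abs_log2fc = min_abs_log2fc
  ), class = "ifn_det_set")
}

#' @export
print.ifn_det_set <- function(x, ...) {
  cat(sprintf("<ifn_det_set> %d up / %d down (padj <= %g, |log2FC| >= %g)\n",
              length(x$up), length(x$down), x$padj_max, x$min_abs_log2fc))
  invisible(x)
}

#' Universally regulated features across treatments
#'
#' Intersection over all treatments of the given direction's DET sets.
#'
#' @param det_sets Named list of [det_filter()] results (or of lists with
#'   `up`/`down`), one per treatment.
#' @param direction `"up"` or `"down"`.
#' @return Character vector of features significant in every treatment.
#' @export
universal_sets <- function(det_sets, direction = c("up", "down")) {
  direction <- match.arg(direction)
  assert_that(length(det_sets) >= 1, "need >= 1 treatment")
  Reduce(intersect, lapply(det_sets, `[[`, direction))
}

#' Subtype-specific features
#'
#' Features significant (in the given direction) for exactly one treatment.
#'
#' @inheritParams universal_sets
#' @return Named list, treatment -> character vector.
#' @export
subtype_specific_sets <- function(det_sets, direction = c("up", "down")) {
  direction <- match.arg(direction)
  sets <- lapply(det_sets, `[[`, direction)
  lapply(setNames(names(sets), names(sets)), function(tr) {
    others <- unique(unlist(sets[setdiff(names(sets), tr)]))
    setdiff(sets[[tr]], others)
  })
}

#' Two-set Venn partition
#'
#' @param set_a,set_b Character vectors.
#' @return List `only_a`, `both`, `only_b`.
#' @export
#' @examples
#' lineage_venn(c("ISG15", "IFI44"), c("IFI44", "LAG3"))
lineage_venn <- function(set_a, set_b) {
  set_a <- unique(set_a)
  set_b <- unique(set_b)
  list(only_a = setdiff(set_a, set_b),
       both = intersect(set_a, set_b),
       only_b = setdiff(set_b, set_a))
}
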