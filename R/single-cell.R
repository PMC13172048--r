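#' Log-normalise a single-cell count matrix
#'
#' Counts-per-10k followed by natural log1p:
#' `x = ln(1 + 1e4 * count / cell_total)`, the transform used by the standard
#' single-cell toolkits' "log normalisation".
#'
#' @param counts Matrix or `dgCMatrix`, genes x cells, with non-negative
#'   entries and no all-zero cell.
#' @param scale_factor Per-cell total after rescaling (default 1e4).
#' @return A matrix of the same class and dimensions.
#' @export
sc_log_normalise <- function(counts, scale_factor = 1e4) {
  totals <- Matrix::colSums(counts)
  zero <- colnames(counts)[totals == 0] %||% which(totals == 0)
  assert_that(all(totals > 0),
              sprintf("all-zero cell(s): %s",
                      paste(head(zero, 5), collapse = ", ")))
  if (inherits(counts, "sparseMatrix")) {
    out <- log1p(counts %*% Matrix::Diagonal(x = scale_factor / totals))
    dimnames(out) <- dimnames(counts)
    methods::as(out, "CsparseMatrix")
  } else {
    log1p(sweep(as.matrix(counts), 2, scale_factor / totals, "*"))
  }
}

#' Single-cell Wilcoxon differential expression
#'
#' Seurat-style `FindMarkers` procedure: a gene is tested when it is detected
#' (count > 0) in at least `min_pct` of cells in at least one group and its
#' fold change passes `logfc_threshold`, where
#' `fc = log2((mean(expm1(x_a)) + 1) / (mean(expm1(x_b)) + 1))` on the
#' log-normalised values. P-values come from [mann_whitney_u()] on the
#' normalised values; adjusted p-values are Bonferroni over the tested genes
#' by default.
#'
#' @param normalised Log-normalised matrix (genes x cells) from
#'   [sc_log_normalise()].
#' @param cells_a,cells_b Column names (barcodes) of the two groups; group A
#'   is the treated/"case" group.
#' @param min_pct Minimum detection fraction in at least one group.
#' @param logfc_threshold Minimum `|fc|` for a gene to be tested.
#' @param adjust `"bonferroni"` (default) or `"BH"`.
#' @return Tibble `feature_id`, `log2fc`, `pct_a`, `pct_b`, `pvalue`, `padj`.
#' @export
sc_wilcoxon_de <- function(normalised, cells_a, cells_b, min_pct = 0.10,
                           logfc_threshold = 0.25,
                           adjust = c("bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  assert_that(length(cells_a) >= 1 && length(cells_b) >= 1,
              "both cell groups must be non-empty")
  missing <- setdiff(c(cells_a, cells_b), colnames(normalised))
  assert_that(length(missing) == 0,
              sprintf("unknown barcode(s): %s",
                      paste(head(missing, 3), collapse = ", ")))
  xa <- normalised[, cells_a, drop = FALSE]
  xb <- normalised[, cells_b, drop = FALSE]
  pct_a <- Matrix::rowSums(xa > 0) / length(cells_a)
  pct_b <- Matrix::rowSums(xb > 0) / length(cells_b)
  mean_a <- Matrix::rowSums(expm1(xa)) / length(cells_a)
  mean_b <- Matrix::rowSums(expm1(xb)) / length(cells_b)
  fc <- log2((mean_a + 1) / (mean_b + 1))
  tested <- (pmax(pct_a, pct_b) >= min_pct) & (abs(fc) >= logfc_threshold)
  idx <- which(tested)
  p <- mwu_rows(cbind(as.matrix(xa[idx, , drop = FALSE]),
                      as.matrix(xb[idx, , drop = FALSE])),
                na = length(cells_a))
  padj <- if (adjust == "bonferroni") {
    pmin(1, p * length(idx))
  } else {
    bh_adjust(p)
  }
  tibble::tibble(
    feature_id = rownames(normalised)[idx],
    log2fc = fc[idx], pct_a = pct_a[idx], pct_b = pct_b[idx],
    pvalue = p, padj = padj
  )
}

# Row-wise Mann-Whitney p-values matching mann_whitney_u() exactly: the
# vectorised normal approximation (tie + continuity corrected) for rows on
# the large-sample path, and the scalar test for rows eligible for the exact
# enumeration (both groups <= 8 and no ties).
mwu_rows <- function(x, na) {
  if (nrow(x) == 0) return(numeric(0))
  nb <- ncol(x) - na
  rs <- rank_sum_rows_cpp(x, na)
  n <- na + nb
  z0 <- rs$U - na * nb / 2
  sigma <- sqrt((na * nb / 12) *
                  ((n + 1) - rs$tiesum / (n * (n - 1))))
  z <- (z0 - sign(z0) * 0.5) / sigma
  p <- 2 * pmin(pnorm(z), pnorm(z, lower.tail = FALSE))
  exact_rows <- which(na <= 8 & nb <= 8 & !rs$has_ties)
  for (i in exact_rows) {
    p[i] <- mann_whitney_u(x[i, seq_len(na)], x[i, na + seq_len(nb)])$p
  }
  pmin(1, p)
}

#' Cell types eligible for per-type differential expression
#'
#' A cell type is eligible when its average cell count per sample is strictly
#' greater than `min_avg`; the denominator is the total number of samples,
#' including samples in which the type does not occur.
#'
#' @param cell_metadata Tibble with `cell_type` and `sample` columns.
#' @param min_avg Strict lower bound on the per-sample average.
#' @return Character vector of eligible cell types.
#' @export
eligible_cell_types <- function(cell_metadata, min_avg = 50) {
  assert_columns(cell_metadata, c("cell_type", "sample"), "cell_metadata")
  n_samples <- dplyr::n_distinct(cell_metadata$sample)
  tab <- table(cell_metadata$cell_type)
  names(tab)[tab / n_samples > min_avg]
}

#' Core ISG set across cell types and treatments
#'
#' Intersection over every (cell type, treatment) differential table of the
#' genes significantly up-regulated at `padj < padj_max` (strict) and fold
#' change at least `min_fold` (log2 scale `>= log2(min_fold)`).
#'
#' @param de_tables Tibble of single-cell DE results with columns
#'   `feature_id`, `log2fc`, `padj`, `cell_type`, `contrast`.
#' @param cell_types,treatments The (type, treatment) grid that must be
#'   covered; defaults to all combinations present.
#' @param padj_max Strict adjusted-p threshold.
#' @param min_fold Minimum fold induction (linear scale).
#' @return Character vector of core gene ids.
#' @export
core_isg_set <- function(de_tables, cell_types = NULL, treatments = NULL,
                         padj_max = 0.05, min_fold = 1.5) {
  assert_columns(de_tables, c("feature_id", "log2fc", "padj", "cell_type",
                              "contrast"), "de_tables")
  cell_types <- cell_types %||% unique(de_tables$cell_type)
  treatments <- treatments %||% unique(de_tables$contrast)
  grid <- tidyr::expand_grid(cell_type = cell_types, contrast = treatments)
  sets <- purrr::pmap(grid, function(cell_type, contrast) {
    d <- de_tables[de_tables$cell_type == cell_type &
                     de_tables$contrast == contrast, ]
    assert_that(nrow(d) > 0,
                sprintf("missing DE table for (%s, %s)", cell_type, contrast))
    d$feature_id[!is.na(d$padj) & d$padj < padj_max &
                   d$log2fc >= log2(min_fold)]
  })
  sort(Reduce(intersect, sets))
}

#' Per-cell ISG score
#'
#' Sums the log-normalised expression of a gene set within each cell. Genes
#' absent from the matrix are reported and skipped; an empty effective set is
#' an error.
#'
#' @param normalised Log-normalised matrix (genes x cells).
#' @param gene_set Character vector of gene ids.
#' @param set_id Label stored with the result.
#' @return Tibble of class `ifn_isg_scores`: `barcode`, `score`, `set_id`,
#'   `set_size`.
#' @export
isg_score <- function(normalised, gene_set, set_id = "isg") {
  assert_that(length(gene_set) >= 1, "`gene_set` must be non-empty")
  present <- intersect(unique(gene_set), rownames(normalised))
  missing <- setdiff(unique(gene_set), present)
  if (length(missing) > 0) {
    warn(sprintf("%d gene(s) absent from the matrix and skipped: %s",
                 length(missing), paste(head(missing, 5), collapse = ", ")))
  }
  assert_that(length(present) >= 1,
              "no gene of the set is present in the matrix")
  scores <- Matrix::colSums(normalised[present, , drop = FALSE])
  out <- tibble::tibble(
    barcode = colnames(normalised) %||% as.character(seq_along(scores)),
    score = as.numeric(scores), set_id = set_id,
    set_size = length(present)
  )
  class(out) <- c("ifn_isg_scores", class(out))
  out
}
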