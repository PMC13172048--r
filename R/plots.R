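#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot motif-cluster association results
#'
#' Dot plot of `-log10(padj)` per motif cluster and treatment; the dashed
#' line marks `padj = 0.05`.
#'
#' @param object An `ifn_association` table from [run_motif_association()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ifn_association <- function(object, ...) {
  d <- dplyr::filter(tibble::as_tibble(object), !is.na(.data$padj))
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$treatment, y = -log10(pmax(.data$padj, 1e-300)),
    colour = .data$cluster_id
  )) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_hline(yintercept = -log10(0.05), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(-log[10] ~ "adjusted p"),
                  colour = "motif cluster",
                  title = "Motif-cluster association with fold changes") +
    ggplot2::theme_minimal()
}

#' Plot per-cell ISG score distributions
#'
#' Violin plot of ISG scores per treatment (optionally faceted by cell type
#' when the scores carry a `cell_type` column).
#'
#' @param object An `ifn_isg_scores` tibble from [isg_score()], joined with
#'   cell metadata (`treatment`, optionally `cell_type`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ifn_isg_scores <- function(object, ...) {
  assert_columns(object, c("score", "treatment"), "isg scores")
  p <- ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(
    x = .data$treatment, y = .data$score
  )) +
    ggplot2::geom_violin(fill = "grey85") +
    ggplot2::geom_jitter(width = 0.15, size = 0.2, alpha = 0.3) +
    ggplot2::labs(x = NULL, y = "ISG score (sum of log expression)",
                  title = "Per-cell ISG score") +
    ggplot2::theme_minimal()
  if ("cell_type" %in% names(object)) {
    p <- p + ggplot2::facet_wrap(~cell_type)
  }
  p
}

#' Bar plot of a two-set Venn partition
#'
#' @param venn A [lineage_venn()] result.
#' @param labels Names of the two sets.
#' @return A ggplot.
#' @export
plot_lineage_venn <- function(venn, labels = c("set A", "set B")) {
  d <- tibble::tibble(
    part = factor(c(sprintf("%s only", labels[1]), "both",
                    sprintf("%s only", labels[2])),
                  levels = c(sprintf("%s only", labels[1]), "both",
                             sprintf("%s only", labels[2]))),
    n = c(length(venn$only_a), length(venn$both), length(venn$only_b))
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$part, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Shared and lineage-specific up-regulated genes") +
    ggplot2::theme_minimal()
}
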