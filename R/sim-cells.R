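#' Generate a synthetic single-cell count matrix
#'
#' Emulates the single-cell arm: one sample per treatment (a single donor),
#' a fixed number of cells per sample split evenly across cell types, and
#' Poisson counts with per-cell rate `library_size x gene_weight x fold`.
#' The fold factor is `2^(true_log2fc x potency)` for genes in the cell
#' type's induced program (shared "core" genes are induced in every type,
#' type-specific genes only in theirs) and 1 otherwise. Heterogeneous genes
#' are induced only in a `Bernoulli(het_responder_frac)` subset of treated
#' cells, emulating bimodal ISG induction. Overdispersion enters through
#' per-cell library-size and per-gene weight variability.
#'
#' @param config An [sim_config()] object.
#' @param truth Ground-truth list from [sim_annotation()]; if
#'   `truth$baseline_tpm` is absent the shared baseline stream is regenerated.
#' @return A list with `counts` (a `dgCMatrix`, genes x cells, rownames =
#'   transcript ids) and `cells` (tibble `barcode`, `cell_type`, `treatment`,
#'   `sample`).
#' @export
sim_single_cell <- function(config, truth) {
  stopifnot(inherits(config, "ifn_sim_config"))
  baseline <- truth$baseline_tpm %||% sim_baseline_tpm(config, truth)
  ids <- names(baseline)
  w <- baseline / sum(baseline)
  non_mock <- setdiff(config$treatments, config$mock)

  lfc_wide <- truth$true_log2fc %>%
    tidyr::pivot_wider(names_from = "treatment", values_from = "true_log2fc")
  lfc <- as.matrix(lfc_wide[match(ids, lfc_wide$transcript_id), non_mock,
                            drop = FALSE])
  rownames(lfc) <- ids

  with_stage_seed(config$seed, "single_cell", {
    blocks <- list()
    meta <- list()
    cell_no <- 0L
    sdlog <- 0.3
    for (tr in config$treatments) {
      types <- rep(config$cell_types,
                   length.out = config$n_cells_per_sample)
      for (ct in config$cell_types) {
        m <- sum(types == ct)
        if (m == 0) next
        lib <- rlnorm(m, log(config$sc_library_size) - sdlog^2 / 2, sdlog)
        fold <- rep(1, length(ids))
        if (tr != config$mock) {
          in_prog <- ids %in% truth$programs[[ct]]
          fold[in_prog] <- 2^lfc[in_prog, tr]
        }
        lambda <- (w * fold) %o% lib
        if (tr != config$mock && length(truth$heterogeneous_ids) > 0) {
          het <- intersect(truth$heterogeneous_ids, truth$programs[[ct]])
          het <- het[het %in% ids]
          for (g in het) {
            non_resp <- runif(m) >= config$het_responder_frac
            lambda[g, non_resp] <- w[[g]] * lib[non_resp]
          }
        }
        cnt <- matrix(rpois(length(lambda), lambda), nrow = length(ids),
                      dimnames = list(ids, NULL))
        barcodes <- sprintf("cell_%05d", cell_no + seq_len(m))
        cell_no <- cell_no + m
        colnames(cnt) <- barcodes
        blocks[[length(blocks) + 1L]] <- Matrix::Matrix(cnt, sparse = TRUE)
        meta[[length(meta) + 1L]] <- tibble::tibble(
          barcode = barcodes, cell_type = ct, treatment = tr, sample = tr
        )
      }
    }
    list(counts = do.call(cbind, blocks), cells = dplyr::bind_rows(meta))
  })
}
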