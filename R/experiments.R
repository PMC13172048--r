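# Seeded recovery and calibration experiments. These are the package's own
# power/calibration checks: each run simulates a fresh experiment under the
# default study conditions and measures whether the analysis recovers the
# planted truth.

#' Planted-motif recovery run
#'
#' Simulates a bulk experiment (default study conditions), runs promoter
#' assignment, motif scoring and motif-cluster association, and reports
#' whether the ISRE-like cluster attains the smallest association p-value
#' for every non-mock treatment.
#'
#' @param seed Integer seed for the simulated experiment.
#' @param config Optional [sim_config()] override (its seed is replaced).
#' @return A list with `isre_first` (logical), `per_treatment` (tibble
#'   `treatment`, `top_cluster`, `isre_p`), and `association` (full table).
#' @export
isre_recovery_run <- function(seed, config = NULL) {
  cfg <- config %||% sim_config(seed = seed)
  cfg$seed <- as.integer(seed)
  sim <- simulate_ifn_experiment(cfg, include_single_cell = FALSE)
  scores <- score_promoters(sim$promoters, sim$genome, sim$library,
                            sim$transcripts)
  assoc <- run_motif_association(sim$bulk$de, sim$bulk$tpm, sim$bulk$samples,
                                 scores$transcript_scores, mock = cfg$mock)
  isre_cluster <- sim$library$clusters$cluster_id[
    sim$library$clusters$pwm_id == sim$library$isre_id]
  per <- assoc %>%
    dplyr::filter(!is.na(.data$p)) %>%
    dplyr::group_by(.data$treatment) %>%
    dplyr::summarise(
      top_cluster = .data$cluster_id[which.min(.data$p)],
      isre_p = .data$p[.data$cluster_id == isre_cluster][1],
      .groups = "drop"
    )
  list(isre_first = nrow(per) > 0 && all(per$top_cluster == isre_cluster),
       per_treatment = per, association = assoc)
}

#' Null-calibration run
#'
#' Same pipeline as [isre_recovery_run()] but with every treatment potency
#' set to zero, so all observed fold changes are noise; reports the number of
#' (cluster, treatment) tests with adjusted p at or below `alpha`.
#'
#' @param seed Integer seed.
#' @param alpha Significance level on the adjusted p-value.
#' @return A list with `n_significant` and `association`.
#' @export
null_association_run <- function(seed, alpha = 0.05) {
  cfg <- sim_config(seed = seed)
  cfg$potency[] <- 0
  out <- isre_recovery_run(seed, config = cfg)
  list(n_significant = sum(out$association$padj <= alpha, na.rm = TRUE),
       association = out$association)
}

#' Core-ISG recovery run
#'
#' Simulates the single-cell arm, runs the per-type Wilcoxon differential
#' expression against mock for every eligible cell type and treatment, and
#' intersects the up-sets into a recovered core set, compared against the
#' planted universal program.
#'
#' @param seed Integer seed.
#' @param config Optional [sim_config()] override (its seed is replaced).
#' @return A list with `exact` (recovered set equals the planted core set),
#'   `recovered`, `planted`, and `sc_de` (the combined DE table).
#' @export
core_recovery_run <- function(seed, config = NULL) {
  cfg <- config %||% sim_config(seed = seed)
  cfg$seed <- as.integer(seed)
  ann <- sim_annotation(cfg)
  sc <- sim_single_cell(cfg, ann$truth)
  norm <- sc_log_normalise(sc$counts)
  eligible <- eligible_cell_types(sc$cells)
  treatments <- setdiff(cfg$treatments, cfg$mock)
  sc_de <- purrr::map_dfr(eligible, function(ct) {
    of_type <- sc$cells$barcode[sc$cells$cell_type == ct]
    mock_cells <- intersect(
      of_type, sc$cells$barcode[sc$cells$treatment == cfg$mock])
    purrr::map_dfr(treatments, function(tr) {
      treated <- intersect(
        of_type, sc$cells$barcode[sc$cells$treatment == tr])
      sc_wilcoxon_de(norm, treated, mock_cells) %>%
        dplyr::mutate(cell_type = ct, contrast = tr)
    })
  })
  recovered <- core_isg_set(sc_de, cell_types = eligible,
                            treatments = treatments)
  list(exact = setequal(recovered, ann$truth$core_ids),
       recovered = recovered, planted = ann$truth$core_ids, sc_de = sc_de)
}
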