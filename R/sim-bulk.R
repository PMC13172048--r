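# Baseline abundance shared by the bulk and single-cell generators.
# Regulated transcripts (true ISGs and their regulated ncRNA partners) are
# drawn from the robustly expressed range: the downstream analyses are defined
# only over robustly expressed transcript groups, so the generator models
# regulated transcripts as reliably detected.
sim_baseline_tpm <- function(config, truth) {
  with_stage_seed(config$seed, "baseline_tpm", {
    ids <- names(truth$effects)
    tpm <- rlnorm(length(ids), config$baseline_meanlog, config$baseline_sdlog)
    regulated <- truth$effects != 0
    tpm[regulated] <- pmax(config$isg_min_tpm, tpm[regulated])
    setNames(tpm, ids)
  })
}

#' Generate synthetic bulk abundance and differential-expression tables
#'
#' Emulates the bulk arm of the stimulation experiment: per-donor TPM and
#' count matrices across all treatments, and one differential-expression
#' table per non-mock treatment. The observed log2 fold change is the true
#' effect times the treatment potency plus Gaussian noise; two-sided p-values
#' come from the normal model with known noise SD (the count-model fitting
#' stage is out of scope and consumed as input downstream), and adjusted
#' p-values are Benjamini-Hochberg, applied separately to coding and
#' non-coding transcript groups.
#'
#' @param config An [sim_config()] object.
#' @param truth Ground-truth list from [sim_annotation()].
#' @return A list with `tpm` and `counts` (tibbles, `transcript_id` plus one
#'   column per sample `donorX_treatment`), `samples` (tibble `sample_id`,
#'   `donor`, `treatment`), `de` (tibble `transcript_id`, `log2fc`, `pvalue`,
#'   `padj`, `contrast`, `feature_class`), and `baseline_tpm`.
#' @export
sim_bulk_tables <- function(config, truth) {
  stopifnot(inherits(config, "ifn_sim_config"))
  assert_that(!is.null(truth$effects) && !is.null(truth$true_log2fc),
              "`truth` must come from sim_annotation()")
  baseline <- sim_baseline_tpm(config, truth)
  ids <- names(baseline)
  coding <- startsWith(ids, "tx_cod_")
  non_mock <- setdiff(config$treatments, config$mock)

  lfc_wide <- truth$true_log2fc %>%
    tidyr::pivot_wider(names_from = "treatment",
                       values_from = "true_log2fc") %>%
    dplyr::arrange(match(.data$transcript_id, ids))
  lfc <- cbind(matrix(0, length(ids), 1,
                      dimnames = list(NULL, config$mock)),
               as.matrix(lfc_wide[, non_mock, drop = FALSE]))
  rownames(lfc) <- ids

  with_stage_seed(config$seed, "bulk_tables", {
    samples <- tidyr::expand_grid(donor = seq_len(config$n_donors),
                                  treatment = config$treatments) %>%
      dplyr::mutate(sample_id = sprintf("donor%d_%s", .data$donor,
                                        .data$treatment))
    lib_factor <- setNames(rlnorm(config$n_donors, log(2), 0.2),
                           seq_len(config$n_donors))

    tpm_mat <- matrix(0, length(ids), nrow(samples),
                      dimnames = list(ids, samples$sample_id))
    cnt_mat <- tpm_mat
    for (k in seq_len(nrow(samples))) {
      mu <- baseline * 2^lfc[, samples$treatment[[k]]] *
        rlnorm(length(ids), 0, 0.15)
      tpm_mat[, k] <- mu
      cnt_mat[, k] <- rnbinom(length(ids),
                              mu = mu * lib_factor[[samples$donor[[k]]]],
                              size = 1 / config$nb_dispersion)
    }

    de <- purrr::map_dfr(non_mock, function(tr) {
      obs <- lfc[, tr] + rnorm(length(ids), 0, config$de_noise_sd)
      p <- pmin(1, 2 * pnorm(-abs(obs) / config$de_noise_sd))
      tibble::tibble(
        transcript_id = ids, log2fc = unname(obs), pvalue = unname(p),
        contrast = tr,
        feature_class = ifelse(coding, "coding", "noncoding")
      ) %>%
        dplyr::group_by(.data$feature_class) %>%
        dplyr::mutate(padj = bh_adjust(.data$pvalue)) %>%
        dplyr::ungroup()
    }) %>%
      dplyr::select("transcript_id", "log2fc", "pvalue", "padj",
                    "contrast", "feature_class")

    list(
      tpm = tibble::as_tibble(tpm_mat, rownames = "transcript_id"),
      counts = tibble::as_tibble(cnt_mat, rownames = "transcript_id"),
      samples = samples, de = de, baseline_tpm = baseline
    )
  })
}
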