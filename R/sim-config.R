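#' Configuration for the synthetic IFN-stimulation experiment
#'
#' Builds and validates the parameter set controlling the synthetic data
#' generator. Defaults emulate the design of a PBMC stimulation study:
#' five type I IFN treatments plus mock, three donors, a treatment-potency
#' ordering with IFN-beta strongest and IFN-alpha1 weakest, ISRE-bearing
#' promoters driving induction, five cell types sharing a core ISG program,
#' bimodally induced ("heterogeneous") genes, and divergent/antisense
#' non-coding RNAs paired with coding neighbours.
#'
#' @param seed Integer master seed; all artifact sub-streams derive from it.
#' @param n_coding_genes,n_noncoding_genes Gene counts (one transcript group
#'   per gene).
#' @param chrom_length Length in bp of the single synthetic chromosome.
#' @param treatments Ordered treatment labels; the first is the mock control.
#' @param potency Named multiplier in `[0, 1]` per treatment scaling the true
#'   effect; mock must be 0 and IFN-beta is the largest by default.
#' @param n_donors Number of donors (bulk replicates).
#' @param frac_isg Fraction of coding genes that are true ISGs.
#' @param effect_log2fc Mean true log2 fold change of an ISG at potency 1.
#' @param de_noise_sd SD of the observed bulk log2FC around its true value.
#' @param cell_types Character vector of cell-type labels.
#' @param core_frac Fraction of ISGs in the shared ("core") single-cell
#'   program induced in every cell type; the remainder are split between
#'   cell types as type-specific genes.
#' @param n_cells_per_sample Cells captured per (treatment) sample.
#' @param frac_heterogeneous Fraction of type-specific ISGs induced in only a
#'   subset of treated cells.
#' @param het_responder_frac Fraction of treated cells responding for a
#'   heterogeneous gene.
#' @param frac_divergent_pairs,frac_antisense_pairs Fractions of non-coding
#'   genes placed head-to-head with, or overlapping antisense to, a coding
#'   neighbour.
#' @param frac_anticorrelated Fraction of regulated paired ncRNAs whose true
#'   effect opposes their coding partner's.
#' @param frac_pls Fraction of transcripts given a promoter-like element
#'   within 500 bp of the TSS (the remainder force imputation).
#' @param frac_high_confidence Fraction of transcripts flagged high-confidence
#'   (the motif-score standardisation reference).
#' @param n_decoy_pwms Number of decoy PWMs accompanying the ISRE-like PWM.
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of baseline
#'   TPM for non-ISG transcripts.
#' @param isg_min_tpm Floor on ISG baseline TPM; ISGs are modelled as robustly
#'   expressed transcript groups.
#' @param nb_dispersion Negative-binomial dispersion of bulk counts.
#' @param sc_library_size Mean per-cell library size (counts).
#'
#' @return A validated list of class `ifn_sim_config`.
#' @export
#' @examples
#' cfg <- sim_config(seed = 1, n_coding_genes = 40, n_noncoding_genes = 10)
#' cfg$potency[["ifnb"]]
sim_config <- function(seed = 1L,
                       n_coding_genes = 800L,
                       n_noncoding_genes = 200L,
                       chrom_length = NULL,
                       treatments = c("mock", "ifna1", "ifna2a", "ifna10",
                                      "ifnb", "ifno"),
                       potency = c(mock = 0, ifna1 = 0.55, ifna2a = 0.7,
                                   ifna10 = 0.8, ifnb = 1, ifno = 0.85),
                       n_donors = 3L,
                       frac_isg = 0.25,
                       effect_log2fc = 3.5,
                       de_noise_sd = 0.3,
                       cell_types = c("mono_classical", "mono_intermediate",
                                      "t_cd4", "nk", "b_cell"),
                       core_frac = 0.3,
                       n_cells_per_sample = 400L,
                       frac_heterogeneous = 0.1,
                       het_responder_frac = 0.5,
                       frac_divergent_pairs = 0.2,
                       frac_antisense_pairs = 0.2,
                       frac_anticorrelated = 0.3,
                       frac_pls = 0.7,
                       frac_high_confidence = 0.6,
                       n_decoy_pwms = 9L,
                       baseline_meanlog = log(30),
                       baseline_sdlog = 1,
                       isg_min_tpm = 10,
                       nb_dispersion = 0.1,
                       sc_library_size = 20000) {
  assert_count(seed, "seed", positive = FALSE)
  assert_count(n_coding_genes, "n_coding_genes")
  assert_count(n_noncoding_genes, "n_noncoding_genes")
  assert_count(n_donors, "n_donors")
  assert_count(n_cells_per_sample, "n_cells_per_sample")
  assert_count(n_decoy_pwms, "n_decoy_pwms")
  assert_that(is.character(treatments) && length(treatments) >= 2 &&
                !anyDuplicated(treatments),
              "`treatments` must be >= 2 unique labels (mock first)")
  mock <- treatments[[1]]
  assert_that(all(treatments %in% names(potency)),
              "`potency` must name every treatment")
  potency <- potency[treatments]
  assert_prob(potency, "potency")
  assert_that(potency[[mock]] == 0, "potency of the mock treatment must be 0")
  for (nm in c("frac_isg", "frac_heterogeneous", "het_responder_frac",
               "frac_divergent_pairs", "frac_antisense_pairs",
               "frac_anticorrelated", "frac_pls", "frac_high_confidence",
               "core_frac")) {
    assert_prob(get(nm), nm)
  }
  assert_that(frac_divergent_pairs + frac_antisense_pairs <= 1,
              "divergent + antisense pair fractions must not exceed 1")
  assert_that(is.character(cell_types) && length(cell_types) >= 1,
              "`cell_types` must be a non-empty character vector")
  n_genes <- n_coding_genes + n_noncoding_genes
  spacing <- 3000L
  chrom_length <- chrom_length %||% as.integer(n_genes * spacing + 2000L)
  assert_count(chrom_length, "chrom_length")
  assert_that(chrom_length >= n_genes * spacing,
              sprintf("chrom_length too small to place %d genes at %d bp spacing",
                      n_genes, spacing))
  structure(
    list(
      seed = as.integer(seed),
      n_coding_genes = as.integer(n_coding_genes),
      n_noncoding_genes = as.integer(n_noncoding_genes),
      chrom = "chrS", chrom_length = chrom_length, gene_spacing = spacing,
      treatments = treatments, mock = mock, potency = potency,
      n_donors = as.integer(n_donors),
      frac_isg = frac_isg, effect_log2fc = effect_log2fc,
      de_noise_sd = de_noise_sd,
      cell_types = cell_types, core_frac = core_frac,
      n_cells_per_sample = as.integer(n_cells_per_sample),
      frac_heterogeneous = frac_heterogeneous,
      het_responder_frac = het_responder_frac,
      frac_divergent_pairs = frac_divergent_pairs,
      frac_antisense_pairs = frac_antisense_pairs,
      frac_anticorrelated = frac_anticorrelated,
      frac_pls = frac_pls, frac_high_confidence = frac_high_confidence,
      n_decoy_pwms = as.integer(n_decoy_pwms),
      baseline_meanlog = baseline_meanlog, baseline_sdlog = baseline_sdlog,
      isg_min_tpm = isg_min_tpm, nb_dispersion = nb_dispersion,
      sc_library_size = sc_library_size
    ),
    class = "ifn_sim_config"
  )
}

#' @export
print.ifn_sim_config <- function(x, ...) {
  cat("<ifn_sim_config>\n")
  cat(sprintf("  seed %d | %d coding + %d non-coding genes on %s (%d bp)\n",
              x$seed, x$n_coding_genes, x$n_noncoding_genes,
              x$chrom, x$chrom_length))
  cat(sprintf("  treatments: %s (mock = %s)\n",
              paste(x$treatments, collapse = ", "), x$mock))
  cat(sprintf("  %d donors | %d cell types x %d cells/sample\n",
              x$n_donors, length(x$cell_types), x$n_cells_per_sample))
  invisible(x)
}
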