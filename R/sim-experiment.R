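#' Simulate a full IFN-stimulation experiment with known ground truth
#'
#' Chains the generator stages: annotation/genome/elements and ground truth
#' ([sim_annotation()]), PWM library ([sim_motif_library()]), promoter
#' assignment ([assign_promoters()]), ISRE-like motif planting into every
#' promoter serving a true ISG ([plant_motifs()], written back into the
#' genome so downstream sequence extraction sees the planted sites), bulk
#' tables ([sim_bulk_tables()]) and, optionally, the single-cell matrix
#' ([sim_single_cell()]). All randomness derives from `config$seed`; the same
#' config yields byte-identical artifacts.
#'
#' @param config An [sim_config()] object.
#' @param include_single_cell Generate the single-cell arm (the most
#'   expensive stage); set `FALSE` for bulk-only studies.
#' @return An object of class `ifn_simulation`: list with `config`, `genome`,
#'   `transcripts`, `elements`, `promoters`, `library`, `truth` (including
#'   `motif_planted` and `planted_sites`), `bulk`, and `sc` (or `NULL`).
#' @export
#' @examples
#' sim <- simulate_ifn_experiment(
#'   sim_config(seed = 7, n_coding_genes = 40, n_noncoding_genes = 10,
#'              n_cells_per_sample = 30)
#' )
#' sim$truth$isg_ids[1:3]
simulate_ifn_experiment <- function(config, include_single_cell = TRUE) {
  stopifnot(inherits(config, "ifn_sim_config"))
  ann <- sim_annotation(config)
  lib <- sim_motif_library(config)
  chrom_len <- setNames(nchar(ann$genome), names(ann$genome))
  promoters <- assign_promoters(ann$transcripts, ann$elements,
                                chrom_len = chrom_len)
  truth <- ann$truth

  serves_isg <- vapply(promoters$transcript_ids,
                       function(ids) any(ids %in% truth$isg_ids), logical(1))
  genome <- ann$genome
  sites <- tibble::tibble(id = character(), offset = integer(),
                          width = integer(), instance = character())
  if (any(serves_isg)) {
    isg_prom <- promoters[serves_isg, ]
    seqs <- extract_sequences(genome, isg_prom)
    planted <- plant_motifs(seqs, names(seqs),
                            lib$pwms[[lib$isre_id]], seed = config$seed)
    sites <- planted$sites
    for (chrom in unique(isg_prom$chrom)) {
      raw_chrom <- charToRaw(genome[[chrom]])
      rows <- which(isg_prom$chrom == chrom)
      for (k in rows) {
        raw_chrom[(isg_prom$start[[k]] + 1L):isg_prom$end[[k]]] <-
          charToRaw(planted$sequences[[k]])
      }
      genome[[chrom]] <- rawToChar(raw_chrom)
    }
  }
  truth$motif_planted <- tibble::tibble(promoter_id = promoters$promoter_id,
                                        planted = serves_isg)
  truth$planted_sites <- sites

  bulk <- sim_bulk_tables(config, truth)
  truth$baseline_tpm <- bulk$baseline_tpm
  sc <- if (include_single_cell) sim_single_cell(config, truth) else NULL

  structure(list(config = config, genome = genome,
                 transcripts = ann$transcripts, elements = ann$elements,
                 promoters = promoters, library = lib, truth = truth,
                 bulk = bulk, sc = sc),
            class = "ifn_simulation")
}

#' @export
print.ifn_simulation <- function(x, ...) {
  cat(sprintf(paste0("<ifn_simulation> seed %d: %d transcripts, %d ISGs, ",
                     "%d promoters, %d PWMs%s\n"),
              x$config$seed, nrow(x$transcripts), length(x$truth$isg_ids),
              nrow(x$promoters), length(x$library$pwms),
              if (is.null(x$sc)) "" else
                sprintf(", %d cells", ncol(x$sc$counts))))
  invisible(x)
}

#' Ground truth of a simulated experiment
#'
#' @param sim An `ifn_simulation` object.
#' @return The truth list (`isg_ids`, `true_log2fc`, `pairs`, `core_ids`,
#'   `programs`, `heterogeneous_ids`, `motif_planted`, ...).
#' @export
ground_truth <- function(sim) {
  stopifnot(inherits(sim, "ifn_simulation"))
  sim$truth
}

#' Write a simulated experiment to disk
#'
#' Writes every external artifact: genome FASTA, annotation (GTF and TSV
#' dialect), promoter-like elements (BED), PWMs (JASPAR PFM text) with the
#' cluster map (TSV), bulk TPM/count matrices and DE tables (TSV), the
#' single-cell MatrixMarket trio with cell metadata, and the ground truth
#' (JSON).
#'
#' @param sim An `ifn_simulation` object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ifn_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  write_annotation(sim$transcripts, file.path(dir, "annotation.gtf"), "gtf")
  write_annotation(sim$transcripts, file.path(dir, "annotation.tsv"), "tsv")
  write_bed(sim$elements, file.path(dir, "pls.bed"))
  write_bed(sim$promoters, file.path(dir, "promoters.bed"))
  write_jaspar_pfm(sim$library$pwms, file.path(dir, "pwms.jaspar"))
  write_cluster_map(sim$library$clusters, file.path(dir, "clusters.tsv"))
  readr::write_tsv(sim$bulk$tpm, file.path(dir, "tpm.tsv"))
  readr::write_tsv(sim$bulk$counts, file.path(dir, "counts.tsv"))
  readr::write_tsv(sim$bulk$de, file.path(dir, "de_tables.tsv"))
  if (!is.null(sim$sc)) {
    write_mtx(sim$sc$counts, sim$sc$cells, file.path(dir, "sc"))
  }
  truth <- sim$truth
  truth$effects <- as.list(truth$effects)
  truth$baseline_tpm <- as.list(truth$baseline_tpm)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
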