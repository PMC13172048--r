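#' Run the full analysis pipeline on a simulated (or assembled) experiment
#'
#' Chains every analysis stage end-to-end: promoter assignment, motif
#' scoring, motif-cluster association with fold changes, bulk DET set
#' algebra, single-cell DE / core-ISG intersection / per-cell ISG scores, and
#' ncRNA pair classification. A manifest records the seed, thresholds, stage
#' record counts and content digests of the main outputs so a run can be
#' checked for reproducibility.
#'
#' @param sim An `ifn_simulation` from [simulate_ifn_experiment()], or a
#'   [sim_config()] (then the experiment is simulated first).
#' @param max_gap,promoter_len Promoter matching parameters (bp).
#' @param hi,lo,min_tpm Motif-association thresholds.
#' @param padj_max,min_log2fc Bulk DET thresholds.
#' @param min_pct,logfc_threshold,sc_padj_max,min_fold Single-cell DE and
#'   core-ISG thresholds.
#' @param min_avg_cells Eligibility threshold (average cells per sample).
#' @param out_dir Optional directory; when given, tables are written there.
#' @return A list of class `ifn_pipeline_result` with elements `promoters`,
#'   `scores`, `association`, `det_sets`, `universal_up`, `universal_down`,
#'   `subtype_specific_up`, `sc_de`, `core_set`, `isg_scores`, `pairs`,
#'   `pair_classes`, and `manifest`.
#' @export
run_ifn_pipeline <- function(sim,
                             max_gap = 500, promoter_len = 350,
                             hi = 2, lo = -1, min_tpm = 10,
                             padj_max = 0.05, min_log2fc = 0.585,
                             min_pct = 0.10, logfc_threshold = 0.25,
                             sc_padj_max = 0.05, min_fold = 1.5,
                             min_avg_cells = 50,
                             out_dir = NULL) {
  if (inherits(sim, "ifn_sim_config")) sim <- simulate_ifn_experiment(sim)
  stopifnot(inherits(sim, "ifn_simulation"))
  counts_of <- list()
  stage <- function(name, value, n) {
    counts_of[[name]] <<- n
    value
  }

  chrom_len <- setNames(nchar(sim$genome), names(sim$genome))
  promoters <- stage("promoters",
                     assign_promoters(sim$transcripts, sim$elements,
                                      chrom_len = chrom_len,
                                      max_gap = max_gap,
                                      target_len = promoter_len),
                     NA)
  counts_of$promoters <- nrow(promoters)

  scores <- score_promoters(promoters, sim$genome, sim$library,
                            sim$transcripts)
  counts_of$motif_score <- nrow(scores$transcript_scores)

  association <- run_motif_association(
    sim$bulk$de, sim$bulk$tpm, sim$bulk$samples, scores$transcript_scores,
    mock = sim$config$mock, hi = hi, lo = lo, min_tpm = min_tpm
  )
  counts_of$motif_assoc <- nrow(association)

  contrasts <- sort(unique(sim$bulk$de$contrast))
  det_sets <- lapply(setNames(contrasts, contrasts), function(tr) {
    det_filter(dplyr::filter(sim$bulk$de, .data$contrast == tr),
               padj_max = padj_max, min_abs_log2fc = min_log2fc)
  })
  universal_up <- universal_sets(det_sets, "up")
  universal_down <- universal_sets(det_sets, "down")
  specific_up <- subtype_specific_sets(det_sets, "up")
  counts_of$de_sets <- length(universal_up)

  sc_de <- NULL
  core_set <- character(0)
  isg_scores <- NULL
  if (!is.null(sim$sc)) {
    norm <- sc_log_normalise(sim$sc$counts)
    eligible <- eligible_cell_types(sim$sc$cells, min_avg = min_avg_cells)
    mock_cells <- sim$sc$cells$barcode[sim$sc$cells$treatment ==
                                         sim$config$mock]
    sc_de <- purrr::map_dfr(eligible, function(ct) {
      purrr::map_dfr(contrasts, function(tr) {
        a <- sim$sc$cells$barcode[sim$sc$cells$cell_type == ct &
                                    sim$sc$cells$treatment == tr]
        b <- intersect(mock_cells,
                       sim$sc$cells$barcode[sim$sc$cells$cell_type == ct])
        sc_wilcoxon_de(norm, a, b, min_pct = min_pct,
                       logfc_threshold = logfc_threshold) %>%
          dplyr::mutate(cell_type = ct, contrast = tr)
      })
    })
    core_set <- if (length(eligible) > 0 && nrow(sc_de) > 0) {
      core_isg_set(sc_de, cell_types = eligible, treatments = contrasts,
                   padj_max = sc_padj_max, min_fold = min_fold)
    } else {
      character(0)
    }
    if (length(core_set) > 0) {
      isg_scores <- isg_score(norm, core_set, set_id = "core")
      isg_scores <- dplyr::left_join(isg_scores, sim$sc$cells,
                                     by = "barcode")
    }
    counts_of$core_isgs <- length(core_set)
    counts_of$isg_score <- if (is.null(isg_scores)) 0L else nrow(isg_scores)
  }

  pairs <- dplyr::bind_rows(pair_divergent(sim$transcripts),
                            pair_antisense(sim$transcripts))
  pair_classes <- if (nrow(pairs) > 0) classify_pairs(pairs, det_sets) else
    list(per_contrast = tibble::tibble(), summary = tibble::tibble())
  counts_of$ncrna_pairs <- nrow(pairs)

  result <- structure(list(
    promoters = promoters, scores = scores, association = association,
    det_sets = det_sets, universal_up = universal_up,
    universal_down = universal_down, subtype_specific_up = specific_up,
    sc_de = sc_de, core_set = core_set, isg_scores = isg_scores,
    pairs = pairs, pair_classes = pair_classes,
    manifest = list(
      seed = sim$config$seed,
      thresholds = list(max_gap = max_gap, promoter_len = promoter_len,
                        hi = hi, lo = lo, min_tpm = min_tpm,
                        padj_max = padj_max, min_log2fc = min_log2fc,
                        min_pct = min_pct, logfc_threshold = logfc_threshold,
                        sc_padj_max = sc_padj_max, min_fold = min_fold,
                        min_avg_cells = min_avg_cells),
      stages = counts_of,
      digests = list(
        association = rlang::hash(association),
        universal_up = rlang::hash(universal_up),
        core_set = rlang::hash(core_set)
      ),
      package_version = as.character(utils::packageVersion("ifnkit"))
    )
  ), class = "ifn_pipeline_result")

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    readr::write_tsv(association, file.path(out_dir, "motif_association.tsv"))
    readr::write_lines(universal_up, file.path(out_dir, "universal_up.txt"))
    readr::write_lines(core_set, file.path(out_dir, "core_isgs.txt"))
    if (!is.null(isg_scores)) {
      readr::write_tsv(isg_scores, file.path(out_dir, "isg_scores.tsv"))
    }
    if (nrow(pair_classes$summary %||% tibble::tibble()) > 0) {
      readr::write_tsv(pair_classes$summary, file.path(out_dir, "pairs.tsv"))
    }
    jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  result
}

#' @export
print.ifn_pipeline_result <- function(x, ...) {
  cat("<ifn_pipeline_result>\n")
  cat(sprintf("  %d promoters | %d association tests | %d universal up\n",
              nrow(x$promoters), nrow(x$association),
              length(x$universal_up)))
  if (!is.null(x$sc_de)) {
    cat(sprintf("  %d core ISGs recovered\n", length(x$core_set)))
  }
  invisible(x)
}

#' @rdname run_ifn_pipeline
#' @param x An `ifn_pipeline_result`.
#' @param ... Unused.
#' @export
glance.ifn_pipeline_result <- function(x, ...) {
  tibble::tibble(
    n_promoters = nrow(x$promoters),
    n_association_tests = sum(!is.na(x$association$p)),
    n_universal_up = length(x$universal_up),
    n_core_isgs = length(x$core_set),
    n_pairs = nrow(x$pairs)
  )
}
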