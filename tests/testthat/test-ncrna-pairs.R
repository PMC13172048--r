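mk_tx <- function(id, start, end, strand, biotype) {
  tibble::tibble(transcript_id = id, gene_id = id, chrom = "chr1",
                 start = start, end = end,
                 tss = ifelse(strand == "+", start, end - 1),
                 strand = strand, biotype = biotype)
}

test_that("pair_divergent pairs head-to-head neighbours, nearest wins", {
  ann <- dplyr::bind_rows(
    mk_tx("nc1", 4601, 5001, "-", "lncRNA"),     # TSS 5000 on -
    mk_tx("cod1", 5400, 6200, "+", "coding"),    # TSS 5400, 400 bp away
    mk_tx("cod2", 5900, 6700, "+", "coding"),    # TSS 5900, further
    mk_tx("cod3", 4000, 4800, "+", "coding")     # TSS 4000: converging
  )
  p <- pair_divergent(ann)
  expect_equal(nrow(p), 1)
  expect_equal(p$coding_id, "cod1")
  expect_equal(p$tss_distance, 400)
  # same strand never pairs
  same <- dplyr::bind_rows(mk_tx("nc2", 100, 500, "+", "lncRNA"),
                           mk_tx("cod4", 900, 1700, "+", "coding"))
  expect_equal(nrow(pair_divergent(same)), 0)
  # beyond the gap: no pair
  far <- dplyr::bind_rows(mk_tx("nc3", 100, 501, "-", "lncRNA"),
                          mk_tx("cod5", 1600, 2400, "+", "coding"))
  expect_equal(nrow(pair_divergent(far)), 0)
})

test_that("pair_antisense pairs overlapping opposite strands, max overlap", {
  ann <- dplyr::bind_rows(
    mk_tx("nc1", 1000, 3000, "-", "lncRNA"),
    mk_tx("cod1", 2000, 6000, "+", "coding"),   # overlap 1000
    mk_tx("cod2", 2900, 3400, "+", "coding")    # overlap 100
  )
  p <- pair_antisense(ann)
  expect_equal(nrow(p), 1)
  expect_equal(p$coding_id, "cod1")
  expect_equal(p$overlap_bp, 1000)
  adjacent <- dplyr::bind_rows(mk_tx("nc2", 100, 500, "-", "lncRNA"),
                               mk_tx("cod3", 500, 900, "+", "coding"))
  expect_equal(nrow(pair_antisense(adjacent)), 0)
})

test_that("classify_pairs distinguishes co-, anti- and unmatched pairs", {
  pairs <- tibble::tibble(ncrna_id = c("nc1", "nc2", "nc3", "nc4"),
                          coding_id = c("c1", "c2", "c3", "c4"))
  ds <- list(ifnb = list(up = c("nc1", "c1", "nc2", "nc3"),
                         down = c("c2")))
  cl <- classify_pairs(pairs, ds)
  per <- cl$per_contrast
  get <- function(nc) per$classification[per$ncrna_id == nc]
  expect_equal(get("nc1"), "co-regulated")
  expect_equal(get("nc2"), "anticorrelated")
  expect_equal(get("nc3"), "unmatched-coding-not-DE")
  expect_true(is.na(get("nc4")))  # ncRNA itself not a DET
  # conservation: classified pairs = paired DET ncRNAs
  expect_equal(sum(!is.na(per$classification)), 3)
  expect_equal(nrow(cl$summary), 3)
})

test_that("planted pairs are recovered and classified from the DE tables", {
  sim <- tiny_sim()
  truth_pairs <- sim$truth$pairs
  geo <- dplyr::bind_rows(pair_divergent(sim$transcripts),
                          pair_antisense(sim$transcripts))
  # geometry recovers every designed pair with the right partner
  merged <- dplyr::inner_join(truth_pairs, geo,
                              by = c("ncrna_id", "orientation"))
  expect_equal(nrow(merged), nrow(truth_pairs))
  expect_equal(merged$coding_id.x, merged$coding_id.y)

  contrasts <- unique(sim$bulk$de$contrast)
  ds <- lapply(setNames(contrasts, contrasts), function(tr) {
    det_filter(sim$bulk$de[sim$bulk$de$contrast == tr, ])
  })
  cl <- classify_pairs(truth_pairs[c("ncrna_id", "coding_id")], ds)
  # whenever both members pass the DET thresholds, the truth label matches
  both_det <- cl$per_contrast[!is.na(cl$per_contrast$classification) &
                  cl$per_contrast$classification != "unmatched-coding-not-DE", ]
  lab <- merge(both_det, truth_pairs, by = c("ncrna_id", "coding_id"))
  expect_gt(nrow(lab), 0)
  expect_true(all(
    (lab$regulation == "co") == (lab$classification == "co-regulated")))
  expect_true(all(
    (lab$regulation == "anti") == (lab$classification == "anticorrelated")))
})
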