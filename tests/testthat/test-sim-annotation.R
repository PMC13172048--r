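test_that("the generator is deterministic and conserves gene counts", {
  cfg <- tiny_config(seed = 11)
  a <- sim_annotation(cfg)
  b <- sim_annotation(cfg)
  expect_identical(a$genome, b$genome)
  expect_identical(a$transcripts, b$transcripts)
  expect_identical(a$elements, b$elements)
  expect_identical(a$truth$true_log2fc, b$truth$true_log2fc)
  expect_equal(nrow(a$transcripts),
               cfg$n_coding_genes + cfg$n_noncoding_genes)
})

test_that("pair table is empty when pairing fractions are zero", {
  cfg <- tiny_config(seed = 3, frac_divergent_pairs = 0,
                     frac_antisense_pairs = 0)
  ann <- sim_annotation(cfg)
  expect_equal(nrow(ann$truth$pairs), 0)
  expect_true(all(ann$transcripts$biotype %in% c("coding", "lncRNA")))
})

test_that("designed pairs have the intended geometry", {
  ann <- sim_annotation(tiny_config(seed = 5, frac_divergent_pairs = 0.4,
                                    frac_antisense_pairs = 0.4))
  tx <- ann$transcripts
  at <- function(id) tx[tx$transcript_id == id, ]
  for (k in seq_len(nrow(ann$truth$pairs))) {
    p <- ann$truth$pairs[k, ]
    nc <- at(p$ncrna_id)
    cod <- at(p$coding_id)
    expect_true(nc$strand != cod$strand)
    if (p$orientation == "divergent") {
      expect_lte(abs(nc$tss - cod$tss), 1000)
      minus_tss <- if (nc$strand == "-") nc$tss else cod$tss
      plus_tss <- if (nc$strand == "-") cod$tss else nc$tss
      expect_lte(minus_tss, plus_tss)  # pointing away from each other
      expect_lte(min(nc$end, cod$end) - max(nc$start, cod$start), 0)
    } else {
      expect_gte(min(nc$end, cod$end) - max(nc$start, cod$start), 1)
    }
  }
})

test_that("full PLS coverage leaves nothing to impute; zero forces it", {
  full <- sim_annotation(tiny_config(seed = 6, frac_pls = 1))
  prom <- assign_promoters(full$transcripts, full$elements,
                           chrom_len = nchar(full$genome[[1]]))
  expect_true(all(prom$source == "matched"))

  none <- sim_annotation(tiny_config(seed = 6, frac_pls = 0))
  expect_equal(nrow(none$elements), 0)
  prom0 <- assign_promoters(none$transcripts, none$elements,
                            chrom_len = nchar(none$genome[[1]]))
  expect_true(all(prom0$source == "imputed"))
})

test_that("ground truth ties effects to ISG identity and pair regulation", {
  ann <- sim_annotation(tiny_config(seed = 8))
  truth <- ann$truth
  non_isg_coding <- setdiff(
    ann$transcripts$transcript_id[ann$transcripts$biotype == "coding"],
    truth$isg_ids)
  lfc <- truth$true_log2fc
  expect_true(all(lfc$true_log2fc[lfc$transcript_id %in% non_isg_coding] == 0))
  expect_true(all(truth$effects[truth$isg_ids] > 0))
  co <- truth$pairs[truth$pairs$regulation == "co", ]
  anti <- truth$pairs[truth$pairs$regulation == "anti", ]
  expect_equal(unname(truth$effects[co$ncrna_id]),
               unname(truth$effects[co$coding_id]))
  expect_equal(unname(truth$effects[anti$ncrna_id]),
               unname(-truth$effects[anti$coding_id]))
  # pair partners exist in the annotation
  expect_true(all(c(truth$pairs$ncrna_id, truth$pairs$coding_id) %in%
                    ann$transcripts$transcript_id))
})

test_that("every planted-motif promoter serves an induced transcript", {
  sim <- tiny_sim()
  planted <- sim$truth$motif_planted
  lfc <- sim$truth$true_log2fc
  induced <- unique(lfc$transcript_id[lfc$true_log2fc > 0])
  for (pid in planted$promoter_id[planted$planted]) {
    ids <- sim$promoters$transcript_ids[[
      which(sim$promoters$promoter_id == pid)]]
    expect_true(any(ids %in% induced))
  }
})
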