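tx1 <- function(tss, strand = "+", id = "t1") {
  tibble::tibble(transcript_id = id, chrom = "chr1", tss = tss,
                 strand = strand)
}
el1 <- function(start, end, id = "e1") {
  tibble::tibble(element_id = id, chrom = "chr1", start = start, end = end)
}

test_that("match_pls applies the edge-distance rule, boundary inclusive", {
  expect_equal(match_pls(tx1(10000), el1(10300, 10500))$gap, 300)
  expect_equal(match_pls(tx1(10000), el1(10500, 10700))$gap, 500)
  expect_equal(nrow(match_pls(tx1(10000), el1(10501, 10700))), 0)
  inside <- match_pls(tx1(10000), el1(9900, 10100))
  expect_equal(inside$gap, 0)
  # multiple qualifying elements are all retained
  both <- match_pls(tx1(10000),
                    dplyr::bind_rows(el1(9400, 9600, "e1"),
                                     el1(10200, 10400, "e2")))
  expect_setequal(both$element_id, c("e1", "e2"))
  # elements on a chromosome with no transcripts are rejected by name
  stray <- el1(100, 300, "stray")
  stray$chrom <- "chrZ"
  expect_error(match_pls(tx1(10000), stray), "chrZ.*stray")
})

test_that("extend_region centres on the floor midpoint and clamps at edges", {
  r <- extend_region(tibble::tibble(start = 100, end = 300), 350, 10000)
  expect_equal(c(r$start, r$end), c(25, 375))
  # already at target length: reproduced up to parity
  r2 <- extend_region(tibble::tibble(start = 1000, end = 1350), 350, 10000)
  expect_equal(c(r2$start, r2$end), c(1000, 1350))
  r3 <- extend_region(tibble::tibble(start = 0, end = 100), 350, 10000)
  expect_equal(c(r3$start, r3$end), c(0, 350))
  expect_error(extend_region(tibble::tibble(start = 0, end = 10), 350, 300),
               "exceeds chromosome length")
})

test_that("extend_region is idempotent", {
  set.seed(1)
  for (i in 1:50) {
    s <- sample.int(5000, 1)
    r <- tibble::tibble(start = s, end = s + sample.int(900, 1))
    once <- extend_region(r, 350, 10000)
    twice <- extend_region(once, 350, 10000)
    expect_identical(once, twice)
    expect_equal(once$end - once$start, 350)
  }
})

test_that("impute_promoter centres on the TSS, strand-agnostic, clamped", {
  r <- impute_promoter(tx1(5000), 10000)
  expect_equal(c(r$start, r$end), c(4825, 5175))
  expect_equal(impute_promoter(tx1(100), 10000)$start, 0)
  expect_identical(impute_promoter(tx1(5000, "-"), 10000)[c("start", "end")],
                   impute_promoter(tx1(5000, "+"), 10000)[c("start", "end")])
  expect_error(impute_promoter(tx1(100), 300), "shorter than 350")
})

test_that("assign_promoters covers every transcript and merges duplicates", {
  two_el <- dplyr::bind_rows(el1(9400, 9600, "e1"), el1(10200, 10400, "e2"))
  out <- assign_promoters(tx1(10000), two_el, chrom_len = 20000)
  expect_equal(nrow(out), 2)
  expect_true(all(out$source == "matched"))

  out0 <- assign_promoters(tx1(10000), el1(50, 60), chrom_len = 20000)
  expect_equal(nrow(out0), 1)
  expect_equal(out0$source, "imputed")

  # two transcripts sharing one element collapse to one region
  txs <- dplyr::bind_rows(tx1(10000, id = "t1"), tx1(10050, id = "t2"))
  shared <- assign_promoters(txs, el1(9900, 10100), chrom_len = 20000)
  expect_equal(nrow(shared), 1)
  expect_setequal(shared$transcript_ids[[1]], c("t1", "t2"))
})

test_that("matched-iff-near holds on random layouts (brute force)", {
  set.seed(99)
  for (i in 1:30) {
    n_tx <- sample(3:8, 1)
    n_el <- sample(1:6, 1)
    txs <- tibble::tibble(
      transcript_id = paste0("t", seq_len(n_tx)), chrom = "chr1",
      tss = sample.int(50000, n_tx), strand = "+"
    )
    start <- sample.int(50000, n_el)
    els <- tibble::tibble(element_id = paste0("e", seq_len(n_el)),
                          chrom = "chr1", start = start,
                          end = start + sample(50:400, n_el, replace = TRUE))
    out <- assign_promoters(txs, els, chrom_len = 60000)
    expect_equal(out$end - out$start, rep(350, nrow(out)))
    expect_setequal(unique(unlist(out$transcript_ids)), txs$transcript_id)
    # brute-force the matched relation
    for (k in seq_len(n_tx)) {
      gaps <- pmax(0, els$start - txs$tss[k], txs$tss[k] - (els$end - 1))
      near <- any(gaps <= 500)
      sources <- out$source[vapply(out$transcript_ids, function(ids)
        txs$transcript_id[k] %in% ids, logical(1))]
      if (near) expect_true("matched" %in% sources)
      else expect_true(all(sources == "imputed"))
    }
  }
})
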