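test_that("filter_robust_bulk requires one fully supported condition", {
  counts <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3"),
    m1 = c(25, 19, 20), m2 = c(30, 25, 20), m3 = c(22, 25, 20),
    s1 = c(0, 19, 5), s2 = c(0, 25, 5), s3 = c(0, 25, 5)
  )
  cond <- setNames(rep(c("mock", "stim"), each = 3),
                   c("m1", "m2", "m3", "s1", "s2", "s3"))
  kept <- filter_robust_bulk(counts, cond)
  expect_setequal(kept, c("t1", "t3"))  # t2: a 19 in every condition
  expect_error(filter_robust_bulk(counts, cond[-1]), "unlabelled")
})

test_that("det_filter applies inclusive thresholds and reports NAs", {
  de <- tibble::tibble(
    feature_id = c("up_edge", "dn", "ns_p", "ns_fc", "na_p"),
    log2fc = c(0.585, -0.7, 3, 0.3, 2),
    padj = c(0.05, 0.01, 0.06, 0.01, NA)
  )
  ds <- det_filter(de)
  expect_setequal(ds$up, "up_edge")
  expect_setequal(ds$down, "dn")
  expect_equal(ds$n_missing_padj, 1)
  expect_length(intersect(ds$up, ds$down), 0)
})

test_that("relaxing thresholds never shrinks a DET set", {
  set.seed(20)
  for (i in 1:20) {
    de <- tibble::tibble(
      feature_id = paste0("f", 1:50),
      log2fc = rnorm(50, 0, 1.5),
      padj = runif(50)
    )
    strict <- det_filter(de, padj_max = 0.05, min_abs_log2fc = 1)
    loose <- det_filter(de, padj_max = 0.2, min_abs_log2fc = 0.3)
    expect_true(all(strict$up %in% loose$up))
    expect_true(all(strict$down %in% loose$down))
    expect_length(intersect(loose$up, loose$down), 0)
  }
})

test_that("universal and subtype-specific set algebra", {
  sets <- list(
    ifnb = list(up = c("A", "B"), down = c("X")),
    ifna1 = list(up = c("A", "C"), down = character(0))
  )
  expect_equal(universal_sets(sets, "up"), "A")
  expect_equal(universal_sets(sets, "down"), character(0))
  spec <- subtype_specific_sets(sets, "up")
  expect_equal(spec$ifnb, "B")
  expect_equal(spec$ifna1, "C")
  # identical sets leave nothing specific
  same <- list(t1 = list(up = c("A", "B")), t2 = list(up = c("A", "B")))
  expect_length(unlist(subtype_specific_sets(same, "up")), 0)
  # specific sets never meet the universal set
  expect_length(intersect(unlist(spec), universal_sets(sets, "up")), 0)
})

test_that("lineage_venn partitions and conserves", {
  v <- lineage_venn(c("a", "b", "c"), c("b", "c", "d"))
  expect_equal(v$only_a, "a")
  expect_setequal(v$both, c("b", "c"))
  expect_equal(v$only_b, "d")
  expect_length(lineage_venn(c("a"), c("b"))$both, 0)
  same <- lineage_venn(c("a", "b"), c("a", "b"))
  expect_length(same$only_a, 0)
  expect_length(same$only_b, 0)
  set.seed(21)
  for (i in 1:20) {
    a <- sample(letters, sample(5:20, 1))
    b <- sample(letters, sample(5:20, 1))
    v <- lineage_venn(a, b)
    expect_equal(length(v$only_a) + length(v$both) + length(v$only_b),
                 length(union(a, b)))
    expect_equal(length(v$only_a) + length(v$both), length(unique(a)))
  }
})

test_that("sets built to the reported lineage sizes partition as expected", {
  monocyte <- paste0("g", 1:229)
  lymphocyte <- c(paste0("g", 1:111), paste0("h", 1:77))
  v <- lineage_venn(monocyte, lymphocyte)
  expect_equal(lengths(v[c("only_a", "both", "only_b")]),
               c(only_a = 118, both = 111, only_b = 77))
})
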