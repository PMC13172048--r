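toy_counts <- function() {
  m <- matrix(c(1, 0, 9999,    # cell1: total 10000
                4, 4, 12,      # cell2
                0, 0, 5),      # cell3
              nrow = 3,
              dimnames = list(c("g1", "g2", "g3"),
                              c("cell1", "cell2", "cell3")))
  m
}

test_that("sc_log_normalise computes ln(1 + 1e4 * count / total)", {
  norm <- sc_log_normalise(toy_counts())
  expect_equal(norm["g1", "cell1"], log(2))  # 1 of 10000 -> ln(1 + 1)
  expect_equal(norm["g2", "cell1"], 0)
  # doubling a cell's counts leaves its normalised values unchanged
  doubled <- toy_counts()
  doubled[, 2] <- doubled[, 2] * 2
  expect_equal(sc_log_normalise(doubled)[, 2],
               sc_log_normalise(toy_counts())[, 2])
  bad <- toy_counts()
  bad[, 3] <- 0
  expect_error(sc_log_normalise(bad), "cell3")
  # sparse input stays sparse with identical values
  sp <- sc_log_normalise(Matrix::Matrix(toy_counts(), sparse = TRUE))
  expect_s4_class(sp, "CsparseMatrix")
  expect_equal(as.matrix(sp), norm)
})

test_that("sc_wilcoxon_de applies detection and fold-change pre-filters", {
  set.seed(30)
  n <- 60
  counts <- rbind(
    low_detect = c(rpois(n, 0.04), rpois(n, 0.07)),   # ~4% / ~7% detected
    small_fc = rep(5, 2 * n),                          # fc ~ 0
    real = c(rpois(n, 8), rpois(n, 1))
  )
  colnames(counts) <- paste0("c", seq_len(2 * n))
  # filler balances the group totals so "small_fc" is not shifted by
  # normalisation against the induced "real" gene
  counts <- rbind(counts, filler = c(rep(3, n), rep(10, n)))
  a <- paste0("c", 1:n)
  b <- paste0("c", (n + 1):(2 * n))
  norm <- sc_log_normalise(counts)
  de <- sc_wilcoxon_de(norm, a, b)
  expect_false("low_detect" %in% de$feature_id)
  expect_false("small_fc" %in% de$feature_id)
  expect_true("real" %in% de$feature_id)
  # internal consistency: reported p equals the scalar test on the same data
  expect_equal(de$pvalue[de$feature_id == "real"],
               mann_whitney_u(as.numeric(norm["real", a]),
                              as.numeric(norm["real", b]))$p)
  # Bonferroni over tested genes
  expect_equal(de$padj, pmin(1, de$pvalue * nrow(de)))
  expect_error(sc_wilcoxon_de(norm, character(0), b), "non-empty")
})

test_that("row-wise rank-sum p-values match the scalar test exactly", {
  set.seed(31)
  x <- matrix(sample(0:4, 25 * 30, replace = TRUE), nrow = 25)
  p_fast <- ifnkit:::mwu_rows(x, na = 12)
  p_ref <- apply(x, 1, function(v) mann_whitney_u(v[1:12], v[13:30])$p)
  expect_equal(p_fast, unname(p_ref), tolerance = 1e-12)
  # exact-path fallback (no ties, both groups <= 8)
  y <- matrix(sample(seq(0.1, 99, by = 0.7), 5 * 12), nrow = 5)
  expect_equal(ifnkit:::mwu_rows(y, na = 6),
               unname(apply(y, 1, function(v)
                 mann_whitney_u(v[1:6], v[7:12])$p)),
               tolerance = 1e-12)
})

test_that("eligible_cell_types uses a strict all-samples average", {
  meta <- tibble::tibble(
    cell_type = c(rep("mono", 301), rep("nk", 300), rep("pdc", 12)),
    sample = "s1"
  )
  meta$sample <- rep(paste0("s", 1:6), length.out = nrow(meta))
  expect_setequal(eligible_cell_types(meta), "mono")  # 301/6 > 50; 300/6 = 50
})

test_that("core_isg_set intersects strictly across the full grid", {
  grid <- tidyr::expand_grid(cell_type = c("mono", "nk"),
                             contrast = c("ifnb", "ifna1"))
  de <- purrr::pmap_dfr(grid, function(cell_type, contrast) {
    tibble::tibble(
      feature_id = c("core", "near_miss", "down"),
      log2fc = c(1.2, 1.2, -2),
      padj = c(1e-4,
               ifelse(cell_type == "nk" && contrast == "ifna1", 0.05, 1e-4),
               1e-6),
      cell_type = cell_type, contrast = contrast
    )
  })
  got <- core_isg_set(de)
  expect_equal(got, "core")  # near_miss fails one pair (padj not < 0.05)
  expect_error(core_isg_set(de, cell_types = c("mono", "missing")),
               "missing DE table")
})

test_that("isg_score sums log expression with additivity and zero floor", {
  norm <- sc_log_normalise(toy_counts())
  s_all <- isg_score(norm, c("g1", "g2"))
  # hand-computed two-cell toy
  expect_equal(s_all$score[s_all$barcode == "cell1"],
               log(1 + 1e4 * 1 / 10000) + 0)
  expect_equal(s_all$score[s_all$barcode == "cell3"], 0)  # no set gene seen
  s1 <- isg_score(norm, "g1")
  s2 <- isg_score(norm, "g2")
  expect_equal(s_all$score, s1$score + s2$score)
  expect_warning(out <- isg_score(norm, c("g1", "ghost")), "absent")
  expect_equal(out$set_size[[1]], 1)
  expect_error(suppressWarnings(isg_score(norm, "ghost")), "no gene")
})
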