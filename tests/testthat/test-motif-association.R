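test_that("partition_transcripts applies inclusive boundaries", {
  scores <- tibble::tibble(transcript_id = c("a", "b", "c", "d"),
                           score = c(2.0, -1.0, 0.5, 3.1))
  part <- partition_transcripts(scores)
  expect_setequal(part$regulated, c("a", "d"))
  expect_setequal(part$unregulated, "b")
  expect_false("c" %in% c(part$regulated, part$unregulated))
  expect_error(partition_transcripts(scores, hi = -1, lo = 2), "exceed")
})

test_that("filter_expressed keeps a transcript expressed in either arm", {
  tpm <- tibble::tibble(
    transcript_id = c("t1", "t2", "t3"),
    m1 = c(12, 9, 10), m2 = c(12, 9, 10), m3 = c(12, 9, 10),
    s1 = c(3, 9, 0), s2 = c(3, 9, 0), s3 = c(3, 9, 0)
  )
  kept <- filter_expressed(tpm, c("s1", "s2", "s3"), c("m1", "m2", "m3"))
  expect_setequal(kept, c("t1", "t3"))  # (12,3) kept; (9,9) out; (10,0) kept
})

test_that("mann_whitney_u: exact example, ties, and degenerate input", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, 0.1)  # 2 of the C(6,3) = 20 arrangements are extreme
  expect_equal(res$U, 0)
  same <- mann_whitney_u(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_equal(same$p, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("mann_whitney_u agrees with a permutation oracle", {
  set.seed(10)
  for (i in 1:15) {
    if (i %% 2 == 1) {
      n_a <- sample(5:12, 1)
      n_b <- sample(5:12, 1)
      vals <- rnorm(n_a + n_b)
    } else {
      n_a <- sample(12:20, 1)
      n_b <- sample(12:20, 1)
      vals <- sample(1:10, n_a + n_b, replace = TRUE)
    }
    a <- vals[seq_len(n_a)]
    b <- vals[-seq_len(n_a)]
    expect_lt(abs(mann_whitney_u(a, b)$p - permutation_mwu_p(a, b, 4000)),
              0.035)
  }
})

test_that("U and p are shift-invariant and label-symmetric", {
  set.seed(11)
  a <- rnorm(9)
  b <- rnorm(7)
  r1 <- mann_whitney_u(a, b)
  r2 <- mann_whitney_u(a + 5, b + 5)
  expect_equal(r1$U, r2$U)
  expect_equal(r1$p, r2$p)
  expect_equal(mann_whitney_u(b, a)$p, r1$p)
  expect_equal(mann_whitney_u(b, a)$U, length(a) * length(b) - r1$U)
})

test_that("normal approximation stays within 0.02 of exact at n = 8", {
  for (u in 0:64) {
    exact <- min(1, 2 * min(stats::pwilcox(u, 8, 8),
                            1 - stats::pwilcox(u - 1, 8, 8)))
    z0 <- u - 32
    z <- (z0 - sign(z0) * 0.5) / sqrt(8 * 8 * 17 / 12)
    approx <- 2 * min(pnorm(z), pnorm(z, lower.tail = FALSE))
    expect_lt(abs(exact - approx), 0.02)
  }
})

test_that("bh_adjust reproduces the step-up procedure", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(0.5, 7)), rep(0.5, 7))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(12)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    ord <- order(p)
    expect_true(all(diff(adj[ord]) >= -1e-12))
  }
})

test_that("run_motif_association emits NA rows for empty arms, outside BH", {
  de <- tibble::tibble(
    transcript_id = paste0("t", 1:20),
    log2fc = c(rep(2, 5), rep(0, 15)),
    contrast = "ifnb"
  )
  tpm <- tibble::tibble(transcript_id = paste0("t", 1:20),
                        d1_mock = 50, d1_ifnb = 50)
  samples <- tibble::tibble(sample_id = c("d1_mock", "d1_ifnb"),
                            treatment = c("mock", "ifnb"))
  scores <- dplyr::bind_rows(
    tibble::tibble(transcript_id = paste0("t", 1:20), cluster_id = "good",
                   score = c(rep(3, 5), rep(-2, 15))),
    tibble::tibble(transcript_id = paste0("t", 1:20), cluster_id = "empty",
                   score = rep(3, 20))  # nobody below lo: empty arm
  )
  res <- run_motif_association(de, tpm, samples, scores)
  empty_row <- res[res$cluster_id == "empty", ]
  expect_true(is.na(empty_row$p))
  expect_true(is.na(empty_row$padj))
  good_row <- res[res$cluster_id == "good", ]
  # single test in the BH pool: padj equals p
  expect_equal(good_row$padj, good_row$p)
  expect_gte(good_row$padj, good_row$p)
  expect_equal(good_row$n_regulated, 5)
  expect_equal(good_row$n_unregulated, 15)
  expect_equal(good_row$median_fc_regulated, 2)
})
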