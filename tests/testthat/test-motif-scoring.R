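mk_scores <- function(m, proms, pwms) {
  matrix(m, nrow = length(proms), dimnames = list(proms, pwms))
}

test_that("reference_standardise matches hand arithmetic and contracts", {
  s <- mk_scores(c(1, 2, 3, 5), c("p1", "p2", "p3", "p4"), "M1")
  z <- reference_standardise(s, c("p1", "p2", "p3"))
  expect_equal(z["p4", 1], 3)         # (5 - 2) / 1
  expect_equal(z["p2", 1], 0)         # raw equals the reference mean
  expect_equal(mean(z[c("p1", "p2", "p3"), 1]), 0, tolerance = 1e-12)
  expect_equal(sd(z[c("p1", "p2", "p3"), 1]), 1, tolerance = 1e-12)
})

test_that("reference_standardise validates its inputs", {
  s <- mk_scores(c(1, 1, 1, 2), c("p1", "p2", "p3", "p4"), "M7")
  expect_error(reference_standardise(s, c("p1", "p2", "p3")), "M7")
  expect_error(reference_standardise(s, c("p1", "nope")), "missing")
  expect_error(reference_standardise(s, "p1"), ">= 2")
})

test_that("cluster_scores: singleton identity and hand oracle", {
  proms <- c("p1", "p2", "p3")
  z <- cbind(A = c(-1, 0, 1), B = c(2, -2, 0), C = c(0.5, 0.5, -1))
  rownames(z) <- proms
  z <- reference_standardise(z, proms)
  clusters <- tibble::tibble(pwm_id = c("A", "B", "C"),
                             cluster_id = c("c1", "c2", "c2"))
  cz <- cluster_scores(z, clusters, proms)
  # singleton cluster: the member z is already mean-0/sd-1 over the
  # reference, so re-standardisation leaves it unchanged
  expect_equal(cz[, "c1"], z[, "A"], tolerance = 1e-12)
  # two-member cluster: standardised sum, computed independently here
  s <- z[, "B"] + z[, "C"]
  expect_equal(cz[, "c2"], (s - mean(s)) / sd(s), tolerance = 1e-12)
  # contracts
  expect_equal(colMeans(cz), c(c1 = 0, c2 = 0), tolerance = 1e-12)
  expect_equal(apply(cz, 2, sd), c(c1 = 1, c2 = 1), tolerance = 1e-12)
  expect_error(cluster_scores(z, clusters[1:2, ], proms), "partition")
})

test_that("transcript scores take the max over associated promoters", {
  cz <- mk_scores(c(-0.5, 2.3, 1.0), c("p1", "p2", "p3"), "c1")
  map <- tibble::tibble(promoter_id = c("p1", "p2", "p2", "p3"),
                        transcript_id = c("t1", "t1", "t2", "t3"))
  ts <- transcript_cluster_scores(cz, map)
  expect_equal(ts$score[ts$transcript_id == "t1"], 2.3)
  expect_equal(ts$score[ts$transcript_id == "t2"], 2.3)
  expect_equal(ts$score[ts$transcript_id == "t3"], 1.0)
  expect_error(transcript_cluster_scores(cz, tibble::tibble(
    promoter_id = "p9", transcript_id = "t9")), "missing")
})

test_that("the full scoring stage matches an independent reimplementation", {
  sim <- tiny_sim()
  proms <- sim$promoters[1:30, ]
  lib <- list(pwms = sim$library$pwms[1:3],
              clusters = sim$library$clusters[
                sim$library$clusters$pwm_id %in%
                  names(sim$library$pwms)[1:3], ])
  res <- score_promoters(proms, sim$genome, lib, sim$transcripts)

  # quadratic-time reference: brute-force scan, then plain-R standardisation
  seqs <- ifnkit:::extract_sequences(sim$genome, proms)
  for (pw in names(lib$pwms)) {
    lo <- pwm_log_odds(lib$pwms[[pw]])
    raw_ref <- vapply(seqs, brute_force_scan, numeric(1), lo = lo)
    expect_equal(unname(res$raw[, pw]), unname(raw_ref), tolerance = 1e-10)
    mu <- mean(raw_ref[res$reference_ids])
    sg <- sd(raw_ref[res$reference_ids])
    expect_equal(unname(res$z[, pw]), unname((raw_ref - mu) / sg),
                 tolerance = 1e-9)
  }

  # standardisation contracts at every stage
  expect_equal(colMeans(res$z[res$reference_ids, ]),
               setNames(rep(0, 3), names(lib$pwms)), tolerance = 1e-9)
  expect_equal(apply(res$cluster_z[res$reference_ids, , drop = FALSE], 2, sd),
               setNames(rep(1, ncol(res$cluster_z)),
                        colnames(res$cluster_z)),
               tolerance = 1e-9)
})
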