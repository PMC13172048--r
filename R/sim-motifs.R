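#' Planted ISRE-like consensus
#'
#' Fixed consensus used for the synthetic ISRE-like PWM: a tandem repeat of
#' the GTTTCA half-site, the motif family bound by the ISGF3 complex at
#' IFN-stimulated response elements. Documented as a constant so recovery
#' experiments are reproducible.
#' @export
isre_consensus <- "AGTTTCAGTTTCA"

#' Generate a synthetic PWM library with cluster membership
#'
#' Builds one strongly informative ISRE-like PWM (from [isre_consensus],
#' dominant-base probability 0.85) plus `n_decoy_pwms` decoys with weaker
#' random informative columns (dominant probability 0.7, widths 8-10). The
#' ISRE-like PWM sits in its own singleton cluster; decoys are grouped into
#' clusters of 1-3 members.
#'
#' @param config An [sim_config()] object.
#' @return A list of class `ifn_motif_library` with elements `pwms` (named
#'   list of 4 x W count matrices, rows A/C/G/T), `clusters` (tibble
#'   `pwm_id`, `cluster_id`), and `isre_id`.
#' @export
sim_motif_library <- function(config) {
  stopifnot(inherits(config, "ifn_sim_config"))
  assert_count(config$n_decoy_pwms, "n_decoy_pwms")
  bases <- c("A", "C", "G", "T")
  consensus_pwm <- function(consensus, dominant, scale = 100) {
    cols <- strsplit(consensus, "")[[1]]
    m <- matrix((1 - dominant) / 3, nrow = 4, ncol = length(cols),
                dimnames = list(bases, NULL))
    for (j in seq_along(cols)) m[cols[[j]], j] <- dominant
    round(m * scale)
  }
  with_stage_seed(config$seed, "motif_library", {
    pwms <- list(ISRE01 = consensus_pwm(isre_consensus, 0.85))
    for (k in seq_len(config$n_decoy_pwms)) {
      # resample decoys similar to the planted consensus (either strand):
      # motif clustering would place such a PWM in the ISRE cluster, and a
      # similar "decoy" would legitimately detect the planted signal
      repeat {
        w <- sample(8:10, 1)
        cons <- paste(sample(bases, w, replace = TRUE), collapse = "")
        if (consensus_similarity(cons, isre_consensus) <= 5) break
      }
      pwms[[sprintf("DECOY%02d", k)]] <- consensus_pwm(cons, 0.7)
    }
    # decoys grouped 1-3 per cluster; ISRE-like alone in its own cluster
    decoy_ids <- setdiff(names(pwms), "ISRE01")
    sizes <- integer(0)
    left <- length(decoy_ids)
    while (left > 0) {
      s <- min(left, sample(1:3, 1))
      sizes <- c(sizes, s)
      left <- left - s
    }
    clusters <- tibble::tibble(
      pwm_id = c("ISRE01", decoy_ids),
      cluster_id = c("C_ISRE", rep(sprintf("C%02d", seq_along(sizes)), sizes))
    )
    structure(list(pwms = pwms, clusters = clusters, isre_id = "ISRE01"),
              class = "ifn_motif_library")
  })
}

# Maximum number of matching positions between a candidate consensus and a
# target consensus (or its reverse complement) over all ungapped offsets.
consensus_similarity <- function(candidate, target) {
  a <- strsplit(candidate, "")[[1]]
  best <- 0L
  for (tgt in c(target, reverse_complement(target))) {
    b <- strsplit(tgt, "")[[1]]
    for (off in -(length(a) - 1):(length(b) - 1)) {
      ia <- seq_along(a)
      ib <- ia + off
      keep <- ib >= 1 & ib <= length(b)
      if (any(keep)) {
        best <- max(best, sum(a[ia[keep]] == b[ib[keep]]))
      }
    }
  }
  best
}

#' @export
print.ifn_motif_library <- function(x, ...) {
  cat(sprintf("<ifn_motif_library> %d PWMs in %d clusters (ISRE-like: %s)\n",
              length(x$pwms), dplyr::n_distinct(x$clusters$cluster_id),
              x$isre_id))
  invisible(x)
}

#' Information content of a PWM, in bits
#'
#' @param pwm A 4 x W count (or probability) matrix with rows A/C/G/T.
#' @param pseudocount Added to every cell before normalisation.
#' @return Total information content (sum over columns of `2 - H(column)`).
#' @export
pwm_information_content <- function(pwm, pseudocount = 0.01) {
  p <- sweep(pwm + pseudocount, 2, colSums(pwm + pseudocount), "/")
  sum(2 + colSums(p * log2(p)))
}

#' Plant motif instances into promoter sequences
#'
#' For each selected promoter sequence, samples one realisation from the PWM's
#' per-column base probabilities and writes it over a uniformly chosen window.
#' Unselected sequences are returned untouched.
#'
#' @param sequences Named character vector of promoter sequences.
#' @param planted_ids Names of the sequences to receive a motif instance.
#' @param pwm A 4 x W count matrix (rows A/C/G/T), e.g. the ISRE-like member
#'   of [sim_motif_library()].
#' @param seed Integer seed controlling sampled instances and positions.
#' @return A list with `sequences` (modified vector, same names/order) and
#'   `sites` (tibble `id`, `offset` 0-based within the sequence, `width`,
#'   `instance`).
#' @export
plant_motifs <- function(sequences, planted_ids, pwm, seed) {
  assert_that(is.character(sequences) && !is.null(names(sequences)),
              "`sequences` must be a named character vector")
  assert_that(all(planted_ids %in% names(sequences)),
              "`planted_ids` must name entries of `sequences`")
  w <- ncol(pwm)
  too_short <- planted_ids[nchar(sequences[planted_ids]) < w]
  assert_that(length(too_short) == 0,
              sprintf("motif width %d exceeds promoter length for: %s",
                      w, paste(head(too_short, 3), collapse = ", ")))
  probs <- sweep(pwm, 2, colSums(pwm), "/")
  bases <- rownames(pwm)
  with_stage_seed(seed, "plant_motifs", {
    sites <- vector("list", length(planted_ids))
    for (k in seq_along(planted_ids)) {
      id <- planted_ids[[k]]
      s <- sequences[[id]]
      inst <- paste(vapply(seq_len(w), function(j) {
        sample(bases, 1, prob = probs[, j])
      }, character(1)), collapse = "")
      off <- sample.int(nchar(s) - w + 1L, 1) - 1L
      substr(s, off + 1L, off + w) <- inst
      sequences[[id]] <- s
      sites[[k]] <- tibble::tibble(id = id, offset = off, width = w,
                                   instance = inst)
    }
    list(sequences = sequences,
         sites = if (length(sites)) dplyr::bind_rows(sites) else
           tibble::tibble(id = character(), offset = integer(),
                          width = integer(), instance = character()))
  })
}
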