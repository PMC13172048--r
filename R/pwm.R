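#' Log-odds matrix from a PWM count matrix
#'
#' Column-normalises counts (with a pseudocount spread over the four bases)
#' and takes base-2 log odds against the background:
#' `entry(b, j) = log2(((counts(b, j) + pseudocount) /
#' (colsum(j) + 4 * pseudocount)) / background(b))`.
#'
#' @param pwm 4 x W non-negative count matrix, rows A/C/G/T.
#' @param background Base frequencies (A, C, G, T); default uniform.
#' @param pseudocount Added to every cell; with `pseudocount = 0`, columns
#'   must not be all zero.
#' @return 4 x W numeric log-odds matrix, rows named A/C/G/T.
#' @export
#' @examples
#' pwm_log_odds(matrix(c(4, 0, 0, 0), 4, 1,
#'                     dimnames = list(c("A", "C", "G", "T"), NULL)),
#'              pseudocount = 0)[1, 1]  # log2(1 / 0.25) = 2
pwm_log_odds <- function(pwm, background = rep(0.25, 4), pseudocount = 0.01) {
  pwm <- as.matrix(pwm)
  assert_that(nrow(pwm) == 4 && ncol(pwm) >= 1,
              "`pwm` must be a 4 x W matrix (rows A, C, G, T)")
  assert_that(all(pwm >= 0), "`pwm` counts must be non-negative")
  assert_that(length(background) == 4 && all(background > 0) &&
                abs(sum(background) - 1) < 1e-6,
              "`background` must be 4 positive frequencies summing to 1")
  assert_that(pseudocount >= 0, "`pseudocount` must be >= 0")
  cs <- colSums(pwm)
  if (pseudocount == 0) {
    assert_that(all(cs > 0), "all-zero PWM column with pseudocount 0")
  }
  probs <- sweep(pwm + pseudocount, 2, cs + 4 * pseudocount, "/")
  lo <- log2(probs / background)
  rownames(lo) <- c("A", "C", "G", "T")
  lo
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector over the alphabet A/C/G/T/N.
#' @return Reverse-complemented character vector.
#' @export
reverse_complement <- function(x) {
  chartr("ACGTN", "TGCAN", vapply(x, function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE))
}

#' Maximum PWM score of a sequence over both strands
#'
#' Slides the log-odds matrix over every window of the sequence and of its
#' reverse complement and returns the maximum score. Ambiguous bases (N)
#' contribute zero. Ties prefer the forward strand, then the smallest
#' window start (0-based, forward coordinates).
#'
#' @param sequence A single DNA string (A/C/G/T/N).
#' @param log_odds 4 x W log-odds matrix from [pwm_log_odds()].
#' @return A list with `score`, `position` (0-based window start) and
#'   `strand` (`"+"` or `"-"`).
#' @export
scan_max_score <- function(sequence, log_odds) {
  assert_that(is.character(sequence) && length(sequence) == 1,
              "`sequence` must be a single string")
  res <- scan_pwm_cpp(sequence, log_odds)
  list(score = res$score[[1]], position = res$position[[1]],
       strand = res$strand[[1]])
}

#' Maximum PWM scores for many sequences
#'
#' Vectorised form of [scan_max_score()].
#'
#' @param sequences Named character vector of DNA strings.
#' @param log_odds 4 x W log-odds matrix.
#' @return Tibble `id`, `score`, `position`, `strand`.
#' @export
scan_max_scores <- function(sequences, log_odds) {
  res <- scan_pwm_cpp(unname(sequences), log_odds)
  tibble::tibble(id = names(sequences) %||% as.character(seq_along(sequences)),
                 score = res$score, position = res$position,
                 strand = res$strand)
}
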