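# Small shared fixtures, built in code. The tiny configuration keeps unit
# tests fast; the default configuration is exercised in test-acceptance.R.

tiny_config <- function(seed = 42, ...) {
  args <- list(seed = seed, n_coding_genes = 40, n_noncoding_genes = 10,
               n_cells_per_sample = 50, n_decoy_pwms = 3)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# lazily built, shared across test files
.fixtures <- new.env(parent = emptyenv())

tiny_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- simulate_ifn_experiment(tiny_config())
  }
  .fixtures$sim
}

# a deterministic 4 x W count matrix with A/C/G/T rownames
toy_pwm <- function(cols) {
  m <- matrix(unlist(cols), nrow = 4,
              dimnames = list(c("A", "C", "G", "T"), NULL))
  m
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
}

# quadratic-time reference scanner, independent of the C++ kernel
brute_force_scan <- function(sequence, lo) {
  w <- ncol(lo)
  score_window <- function(s) {
    chars <- strsplit(s, "")[[1]]
    sum(vapply(seq_along(chars), function(j) {
      if (chars[j] == "N") 0 else lo[chars[j], j]
    }, numeric(1)))
  }
  rc <- chartr("ACGTN", "TGCAN",
               paste(rev(strsplit(sequence, "")[[1]]), collapse = ""))
  windows <- function(s) {
    vapply(seq_len(nchar(s) - w + 1),
           function(p) score_window(substr(s, p, p + w - 1)), numeric(1))
  }
  max(c(windows(sequence), windows(rc)))
}

# permutation reference for the two-sided Mann-Whitney p-value
permutation_mwu_p <- function(a, b, n_perm = 10000) {
  u_stat <- function(x, y) {
    r <- rank(c(x, y))
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  }
  obs <- abs(u_stat(a, b) - length(a) * length(b) / 2)
  pool <- c(a, b)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample.int(length(pool), length(a))
    u <- u_stat(pool[idx], pool[-idx])
    if (abs(u - length(a) * length(b) / 2) >= obs - 1e-9) hits <- hits + 1L
  }
  hits / n_perm
}
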