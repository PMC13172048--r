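# Internal validation and seeding helpers.

`%||%` <- function(x, y) if (is.null(x)) y else x

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) abort(msg, class = "ifnkit_error")
  invisible(TRUE)
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  assert_that(
    length(missing) == 0,
    sprintf("`%s` is missing required column(s): %s",
            what, paste(missing, collapse = ", "))
  )
}

assert_prob <- function(x, name) {
  assert_that(is.numeric(x) && all(is.finite(x)) && all(x >= 0 & x <= 1),
              sprintf("`%s` must lie in [0, 1]", name))
}

assert_count <- function(x, name, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x) &&
    (if (positive) x > 0 else x >= 0)
  assert_that(ok, sprintf("`%s` must be a %s integer", name,
                          if (positive) "positive" else "non-negative"))
}

# Deterministic per-stage sub-seed so that artifacts have independent,
# reproducible random streams derived from one master seed. Kept < 2^31.
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_stage_seed <- function(seed, stage, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derive_seed(seed, stage))
  force(code)
}

# Uppercase ACGTN check used by sequence readers.
assert_dna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGTN]", x)
  assert_that(!any(bad),
              sprintf("%s contains characters outside A/C/G/T/N", what))
}
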