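# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_hbgru <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "hbgru_error")))
}

validation_error <- function(fmt, ...) {
  stop_hbgru(fmt, ..., class = "hbgru_validation_error")
}

parse_error <- function(fmt, ...) {
  stop_hbgru(fmt, ..., class = "hbgru_parse_error")
}

format_error <- function(fmt, ...) {
  stop_hbgru(fmt, ..., class = "hbgru_format_error")
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    validation_error("`%s` must be a single number in [%s, %s]", name, lower, upper)
  }
  invisible(x)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# One whitespace-normalized string: tabs/newlines collapse to single spaces.
squash_ws <- function(x) {
  x <- gsub("[\t\r\n]+", " ", x)
  gsub(" {2,}", " ", trimws(x))
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}
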